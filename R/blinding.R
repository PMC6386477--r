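## ---- keyed sealing -------------------------------------------------------
## The treatment map is stored only in sealed form: plaintext is serialized,
## XOR-ed with a keystream derived from the key and a per-seal salt, and an
## Adler-32 checksum of the plaintext is kept so that decryption with a
## wrong key fails loudly.  This is a keyed sealing with an integrity check,
## not vetted cryptography; see the methods vignette for the limitation.

.key_seed <- function(key) {
  b <- utf8ToInt(key)
  s <- 0
  for (x in b) s <- (s * 131 + x) %% 2147483647
  as.integer(s)
}

.keystream <- function(key, salt, n) {
  had <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", globalenv()) else NULL
  set.seed(.key_seed(paste0(key, ":", salt)))
  ks <- as.raw(sample.int(256L, n, replace = TRUE) - 1L)
  if (had) assign(".Random.seed", old, globalenv())
  else rm(".Random.seed", envir = globalenv())
  ks
}

.adler32 <- function(r) {
  x <- as.integer(r)
  a <- 1; b <- 0
  # chunked so the cumulative sums stay well inside double precision
  for (start in seq(1, length(x), by = 4096)) {
    chunk <- x[start:min(start + 4095, length(x))]
    ca <- a + cumsum(chunk)
    b <- (b + sum(ca %% 65521)) %% 65521
    a <- ca[length(ca)] %% 65521
  }
  sprintf("%04x%04x", b, a)
}

.seal <- function(obj, key, salt) {
  pt <- serialize(obj, NULL, version = 2)
  ks <- .keystream(key, salt, length(pt))
  structure(list(version = 1L, salt = salt, n = length(pt),
                 check = .adler32(pt),
                 cipher = as.raw(bitwXor(as.integer(pt), as.integer(ks)))),
            class = "sealed_arm_map")
}

.unseal <- function(sealed, key) {
  ks <- .keystream(key, sealed$salt, sealed$n)
  pt <- as.raw(bitwXor(as.integer(sealed$cipher), as.integer(ks)))
  if (!identical(.adler32(pt), sealed$check))
    .err("auth_error", "unsealing failed: wrong key or corrupted map")
  unserialize(pt)
}

#' @export
print.sealed_arm_map <- function(x, ...) {
  cat("<sealed arm map> ", x$n, "bytes, salt", x$salt, "\n")
  invisible(x)
}

## ---- allocation list -----------------------------------------------------

## bottle code: "B" + zero-padded integer + one checksum letter
.bottle_codes <- function(idx) {
  chk <- LETTERS[((idx * 7919L) %% 26L) + 1L]
  sprintf("B%06d%s", idx, chk)
}

#' Generate a blinded bottle allocation list
#'
#' Pre-generates bottle codes in randomized blocks of four, each block a
#' random permutation of two metformin and two placebo bottles, so the
#' cumulative treatment ratio is exactly 1:1 after every whole block.  The
#' list is a pure function of `seed` and is reproduced byte-for-byte by the
#' same seed.
#'
#' @param n_bottles positive multiple of 4.
#' @param seed integer seed.
#' @return an `allocation_list` data frame with columns `code`, `block_id`,
#'   `position`, `treatment`.  This clear-text list exists for the
#'   manufacturer and for sealing; inside a trial only the sealed copy and
#'   the blinded labels are kept (see [attach_allocation()]).
#' @examples
#' al <- generate_allocation_list(8, seed = 42)
#' table(al$treatment)
#' @export
generate_allocation_list <- function(n_bottles, seed) {
  if (!is.numeric(n_bottles) || length(n_bottles) != 1L || n_bottles < 4 ||
      n_bottles %% 4 != 0)
    .err("validation_error",
         "n_bottles must be a positive multiple of 4 (blocks of 2+2)")
  n_bottles <- as.integer(n_bottles)
  n_blocks <- n_bottles %/% 4L
  had <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", globalenv()) else NULL
  set.seed(as.integer(seed))
  ## the 6 distinct orderings of {M,M,P,P}; one drawn uniformly per block
  arr <- rbind(c("M","M","P","P"), c("M","P","M","P"), c("M","P","P","M"),
               c("P","M","M","P"), c("P","M","P","M"), c("P","P","M","M"))
  pick <- sample.int(6L, n_blocks, replace = TRUE)
  if (had) assign(".Random.seed", old, globalenv())
  else rm(".Random.seed", envir = globalenv())
  trt <- as.vector(t(arr[pick, , drop = FALSE]))
  trt <- ifelse(trt == "M", "metformin", "placebo")
  out <- data.frame(
    code = .bottle_codes(seq_len(n_bottles)),
    block_id = rep(seq_len(n_blocks), each = 4L),
    position = rep(1:4, n_blocks),
    treatment = trt,
    stringsAsFactors = FALSE
  )
  attr(out, "seed") <- as.integer(seed)
  class(out) <- c("allocation_list", "data.frame")
  out
}

#' Register an allocation list with a trial and seal the treatments
#'
#' Draws the X/Y alias assignment (which label means metformin) once from
#' the trial's seeded stream, stores the operational bottle table carrying
#' only the blinded labels, and seals the per-bottle treatment table plus
#' the alias map under `key`.  After this call the clear list should exist
#' only in the manufacturer export.
#'
#' @param tr a [trial_new()] object.
#' @param alloc an [generate_allocation_list()] result.
#' @param key sealing key string (held outside the operational store).
#' @param date audit date.
#' @return the trial, invisibly.
#' @export
attach_allocation <- function(tr, alloc, key, date = Sys.Date()) {
  stopifnot(inherits(tr, "trial"), inherits(alloc, "allocation_list"))
  if (length(tr$b_code))
    .err("state_error", "trial already has an allocation list")
  if (!is.character(key) || !nzchar(key))
    .err("validation_error", "sealing key must be a non-empty string")
  flip <- .with_rng(tr, stats::runif(1)) < 0.5
  arm_map <- if (flip) c(X = "metformin", Y = "placebo")
             else      c(X = "placebo",   Y = "metformin")
  salt <- sprintf("%08x", as.integer(floor(.with_rng(tr, stats::runif(1)) *
                                           2147483647)))
  tr$sealed <- .seal(list(arm_map = arm_map,
                          bottle = stats::setNames(alloc$treatment,
                                                   alloc$code)),
                     key, salt)
  lab <- names(arm_map)[match(alloc$treatment, arm_map)]
  tr$b_code   <- alloc$code
  tr$b_block  <- alloc$block_id
  tr$b_pos    <- alloc$position
  tr$b_label  <- lab
  tr$b_status <- rep(.ST_GENERATED, nrow(alloc))
  tr$b_batch  <- rep(NA_character_, nrow(alloc))
  tr$b_expiry <- rep(NA_real_, nrow(alloc))
  tr$fefo <- list(X = integer(0), Y = integer(0))
  tr$fefo_head <- list(X = 1L, Y = 1L)
  .audit(tr, date, "system", "administrator", "generate_allocation", "trial",
         paste0("n_bottles=", nrow(alloc), ";n_blocks=", max(alloc$block_id)))
  invisible(tr)
}

#' Manufacturer packaging export
#'
#' The only artifact in which treatment names leave the system: a CSV of
#' bottle code and treatment, the sole information available to the
#' supplier.  The schema has no participant field at all.
#'
#' @param alloc an [generate_allocation_list()] result.
#' @param path optional CSV output path.
#' @return data frame with columns `code` and `treatment`, invisibly if
#'   `path` is given.
#' @export
export_manufacturer_list <- function(alloc, path = NULL) {
  stopifnot(inherits(alloc, "allocation_list"))
  out <- data.frame(code = alloc$code, treatment = alloc$treatment,
                    stringsAsFactors = FALSE)
  if (!is.null(path)) {
    utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
    return(invisible(out))
  }
  out
}

#' Blinded operational view of a bottle
#'
#' @param tr a [trial_new()] object.
#' @param code bottle code.
#' @return list with `code`, `block_id`, `position`, `status`,
#'   `blinded_treatment` (X/Y — never a drug name), `batch_id`,
#'   `expiry_date`.
#' @export
operational_view <- function(tr, code) {
  stopifnot(inherits(tr, "trial"))
  j <- match(code, tr$b_code)
  if (is.na(j)) .err("lookup_error", paste0("unknown bottle code: ", code))
  structure(list(code = tr$b_code[j], block_id = tr$b_block[j],
                 position = tr$b_pos[j], status = .status_chr(tr$b_status[j]),
                 blinded_treatment = tr$b_label[j],
                 batch_id = tr$b_batch[j],
                 expiry_date = .as_date(tr$b_expiry[j])),
            class = "operational_view")
}

#' @export
print.operational_view <- function(x, ...) {
  cat("bottle", x$code, "| block", x$block_id, "pos", x$position,
      "| status", x$status, "| label", x$blinded_treatment, "\n")
  if (!is.na(x$batch_id))
    cat("  batch", x$batch_id, "expires", format(x$expiry_date), "\n")
  invisible(x)
}

#' Emergency unblinding
#'
#' Decrypts a randomized participant's treatment.  Restricted to the
#' principal investigator and intended only for major medical conditions or
#' hospital admission; every call appends an audit event recording the
#' actor, date and reason.
#'
#' @param tr a [trial_new()] object.
#' @param id participant identifier.
#' @param actor actor identifier.
#' @param role actor role; must be `"PI"`.
#' @param reason non-empty reason string.
#' @param key the sealing key.
#' @param date event date.
#' @return the treatment name, `"metformin"` or `"placebo"`.
#' @export
break_blind <- function(tr, id, actor, role, reason, key,
                        date = Sys.Date()) {
  stopifnot(inherits(tr, "trial"))
  if (!identical(role, "PI"))
    .err("auth_error",
         "authorization error: only the PI may break the blind")
  if (!is.character(reason) || length(reason) != 1L || !nzchar(reason))
    .err("validation_error", "a non-empty reason is required")
  i <- .pidx(tr, id)
  if (is.na(tr$p_label[i]))
    .err("state_error",
         paste0(id, " has no blinded assignment (state ", tr$p_state[i], ")"))
  if (is.null(tr$sealed))
    .err("state_error", "no sealed arm map attached to this trial")
  m <- .unseal(tr$sealed, key)
  tr$n_unseal <- tr$n_unseal + 1L
  trt <- unname(m$arm_map[tr$p_label[i]])
  .audit(tr, date, actor, role, "break_blind", id,
         paste0("reason=", reason, ";treatment=", trt))
  trt
}
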