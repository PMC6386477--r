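## On-disk bundle: plain CSV/JSON/JSONL files in one directory, UTF-8,
## ISO-8601 dates, deterministic column order.  The sealed arm map's cipher
## is hex-encoded so the whole store stays text.

.raw_to_hex <- function(r) paste(sprintf("%02x", as.integer(r)),
                                 collapse = "")
.hex_to_raw <- function(h) {
  n <- nchar(h) / 2
  as.raw(strtoi(substring(h, 2 * seq_len(n) - 1, 2 * seq_len(n)), 16L))
}

.iso <- function(x) ifelse(is.na(x), "", format(.as_date(x)))
.uniso <- function(x) {
  out <- rep(NA_real_, length(x))
  nz <- !is.na(x) & nzchar(x)
  out[nz] <- as.numeric(as.Date(x[nz]))
  out
}

#' Save a trial to a directory bundle
#'
#' Writes `participants.csv`, `bottles.csv`, `batches.csv`, `register.csv`,
#' `audit.jsonl` (one event per line, append-only semantics) and
#' `state.json` (config, ledgers, sealed map, RNG state).  The bundle is
#' plain text and round-trips exactly through [load_trial()].
#'
#' @param tr a [trial_new()] object.
#' @param dir target directory (created if needed).
#' @return `dir`, invisibly.
#' @export
save_trial <- function(tr, dir) {
  stopifnot(inherits(tr, "trial"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(d, f) utils::write.csv(d, file.path(dir, f),
                                       row.names = FALSE, na = "")
  p <- data.frame(
    participant_id = tr$p_id, sex = tr$p_sex, birth_date = .iso(tr$p_birth),
    family_id = tr$p_family, is_proband = tr$p_proband,
    consent_date = .iso(tr$p_consent), state = tr$p_state,
    diet_arm = tr$p_arm, treatment_label = tr$p_label,
    dose_level = tr$p_dose, registration_complete = tr$p_regcomplete,
    eligible = tr$p_eligible, runin_start = .iso(tr$p_runin_start),
    runin_ae = tr$p_runin_ae, randomized_date = .iso(tr$p_rand_date),
    treatment_end = .iso(tr$p_trt_end), next_due = .iso(tr$p_next_due),
    anniversary = .iso(tr$p_anniv), stringsAsFactors = FALSE)
  w(p, "participants.csv")
  b <- data.frame(code = tr$b_code, block_id = tr$b_block,
                  position = tr$b_pos, label = tr$b_label,
                  status = .status_chr(tr$b_status), batch_id = tr$b_batch,
                  expiry_date = .iso(tr$b_expiry), stringsAsFactors = FALSE)
  w(b, "bottles.csv")
  k <- data.frame(batch_id = tr$k_id, order_id = tr$k_order,
                  load_date = .iso(tr$k_load), expiry_date = .iso(tr$k_expiry),
                  n_bottles = tr$k_n, stringsAsFactors = FALSE)
  w(k, "batches.csv")
  r <- allocation_register(tr)
  r$date <- format(r$date); r$next_due <- format(r$next_due)
  w(r, "register.csv")

  au <- trial_audit(tr)
  lines <- vapply(seq_len(nrow(au)), function(i) {
    jsonlite::toJSON(list(date = format(au$date[i]), actor = au$actor[i],
                          role = au$actor_role[i], action = au$action[i],
                          subject = au$subject[i], payload = au$payload[i]),
                     auto_unbox = TRUE)
  }, character(1))
  writeLines(lines, file.path(dir, "audit.jsonl"), useBytes = TRUE)

  sealed <- if (is.null(tr$sealed)) NULL else
    list(version = tr$sealed$version, salt = tr$sealed$salt,
         n = tr$sealed$n, check = tr$sealed$check,
         cipher = .raw_to_hex(tr$sealed$cipher))
  state <- list(seed = tr$seed, config = tr$config,
                led_diet = as.vector(tr$led_diet),
                led_trt_sex = as.vector(tr$led_trt_sex),
                led_trt_age = as.vector(tr$led_trt_age),
                sealed = sealed,
                n_unseal = tr$n_unseal, runin_stock = tr$runin_stock,
                runin_dispensed = tr$runin_dispensed,
                rng_state = tr$rng_state)
  jsonlite::write_json(state, file.path(dir, "state.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' Load a trial from a directory bundle
#'
#' @param dir directory written by [save_trial()].
#' @return a `trial` object; `load_trial(save_trial(tr, d))` reproduces
#'   `tr` exactly (the FEFO queues are rebuilt from the bottle table).
#' @export
load_trial <- function(dir) {
  if (!file.exists(file.path(dir, "state.json")))
    .err("lookup_error", paste0("no trial store at ", dir))
  state <- jsonlite::read_json(file.path(dir, "state.json"),
                               simplifyVector = TRUE)
  tr <- trial_new(seed = state$seed, config = as.list(state$config))
  tr$led_diet[] <- as.integer(state$led_diet)
  tr$led_trt_sex[] <- as.integer(state$led_trt_sex)
  tr$led_trt_age[] <- as.integer(state$led_trt_age)
  tr$n_unseal <- as.integer(state$n_unseal)
  tr$runin_stock <- as.integer(state$runin_stock)
  tr$runin_dispensed <- as.integer(state$runin_dispensed)
  tr$rng_state <- as.integer(state$rng_state)
  if (!is.null(state$sealed))
    tr$sealed <- structure(list(version = state$sealed$version,
                                salt = state$sealed$salt,
                                n = state$sealed$n,
                                check = state$sealed$check,
                                cipher = .hex_to_raw(state$sealed$cipher)),
                           class = "sealed_arm_map")

  rd <- function(f, classes) utils::read.csv(file.path(dir, f),
                                             stringsAsFactors = FALSE,
                                             colClasses = classes,
                                             na.strings = "")
  p <- rd("participants.csv", NA)
  if (nrow(p)) {
    tr$p_id <- as.character(p$participant_id); tr$p_sex <- p$sex
    tr$p_birth <- .uniso(p$birth_date)
    tr$p_family <- as.character(p$family_id)
    tr$p_proband <- as.logical(p$is_proband)
    tr$p_consent <- .uniso(p$consent_date); tr$p_state <- p$state
    tr$p_arm <- as.character(p$diet_arm)
    tr$p_label <- as.character(p$treatment_label)
    tr$p_dose <- p$dose_level
    tr$p_regcomplete <- as.logical(p$registration_complete)
    tr$p_eligible <- as.logical(p$eligible)
    tr$p_runin_start <- .uniso(p$runin_start)
    tr$p_runin_ae <- as.logical(p$runin_ae)
    tr$p_rand_date <- .uniso(p$randomized_date)
    tr$p_trt_end <- .uniso(p$treatment_end)
    tr$p_next_due <- .uniso(p$next_due)
    tr$p_anniv <- .uniso(p$anniversary)
    ## accrual-trend cache, rebuilt from the roster
    tr$rand_times <- sort(tr$p_rand_date[!is.na(tr$p_rand_date)])
  }
  b <- rd("bottles.csv", NA)
  if (nrow(b)) {
    tr$b_code <- as.character(b$code); tr$b_block <- as.integer(b$block_id)
    tr$b_pos <- as.integer(b$position); tr$b_label <- b$label
    tr$b_status <- match(b$status, .ST_LEVELS)
    tr$b_batch <- as.character(b$batch_id)
    tr$b_expiry <- .uniso(b$expiry_date)
    tr$fefo_head <- list(X = 1L, Y = 1L)
    for (lab in c("X", "Y")) {
      j <- which(tr$b_label == lab & tr$b_status == .ST_IN_STOCK)
      tr$fefo[[lab]] <- j[order(tr$b_expiry[j])]
    }
  }
  k <- rd("batches.csv", NA)
  if (nrow(k)) {
    tr$k_id <- as.character(k$batch_id)
    tr$k_order <- as.character(k$order_id)
    tr$k_load <- .uniso(k$load_date); tr$k_expiry <- .uniso(k$expiry_date)
    tr$k_n <- as.integer(k$n_bottles)
  }
  r <- rd("register.csv", NA)
  if (nrow(r)) {
    for (ri in seq_len(nrow(r))) {
      assign(as.character(ri),
             list(pid = as.character(r$participant_id[ri]),
                  date = .uniso(r$date[ri]), step = r$step[ri],
                  n = as.integer(r$n_bottles[ri]),
                  codes = as.character(r$bottle_codes[ri]),
                  expiries = as.numeric(as.Date(strsplit(
                    as.character(r$expiry_dates[ri]), ",")[[1]])),
                  tpd = as.integer(r$tablets_per_day[ri]),
                  days = as.integer(r$days_covered[ri]),
                  nxt = .uniso(r$next_due[ri])),
             envir = tr$reg_env)
    }
    tr$reg_n <- nrow(r)
  }
  au_lines <- readLines(file.path(dir, "audit.jsonl"))
  for (ln in au_lines) {
    e <- jsonlite::fromJSON(ln)
    .audit(tr, e$date, e$actor, e$role, e$action, e$subject,
           if (is.null(e$payload)) "" else e$payload)
  }
  tr
}

#' Structural equality of two trials
#'
#' @param a,b trials.
#' @return `TRUE` if every roster, inventory, batch, register, ledger and
#'   audit field matches.
#' @export
trial_equal <- function(a, b) {
  fields <- c("p_id", "p_sex", "p_birth", "p_family", "p_proband",
              "p_consent", "p_state", "p_arm", "p_label", "p_dose",
              "p_regcomplete", "p_eligible", "p_runin_start", "p_runin_ae",
              "p_rand_date", "p_trt_end", "p_next_due", "p_anniv",
              "b_code", "b_block", "b_pos", "b_label", "b_status",
              "b_batch", "b_expiry", "k_id", "k_order", "k_load",
              "k_expiry", "k_n",
              "led_diet", "led_trt_sex", "led_trt_age",
              "runin_stock", "runin_dispensed", "n_unseal")
  for (f in fields) {
    av <- a[[f]]; bv <- b[[f]]
    if (is.matrix(av)) { av <- as.vector(av); bv <- as.vector(bv) }
    if (!isTRUE(all.equal(unname(av), unname(bv)))) return(FALSE)
  }
  if (!identical(a$au_n, b$au_n) || !identical(a$reg_n, b$reg_n))
    return(FALSE)
  identical(trial_audit(a), trial_audit(b)) &&
    identical(allocation_register(a), allocation_register(b))
}

#' Validate a trial store
#'
#' Replays the audit log and checks it reconstructs every participant's
#' state, and checks inventory conservation.
#'
#' @param tr a trial (or a store directory path).
#' @return `TRUE` invisibly on success; raises a validation error otherwise.
#' @export
validate_store <- function(tr) {
  if (is.character(tr)) tr <- load_trial(tr)
  if (!isTRUE(audit_replay_ok(tr)))
    .err("validation_error",
         "audit replay does not reconstruct the participant states")
  if (!inventory_conservation(tr))
    .err("validation_error", "inventory conservation violated")
  invisible(TRUE)
}
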