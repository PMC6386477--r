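#' @keywords internal
"_PACKAGE"

## Dates are stored internally as numeric days since 1970-01-01 so that the
## simulator can do integer day arithmetic; accessors convert back to Date.
.day <- function(x) {
  if (inherits(x, "Date")) return(as.numeric(x))
  if (is.character(x) || is.factor(x)) return(as.numeric(as.Date(as.character(x))))
  as.numeric(x)
}

## numeric days since 1970-01-01 -> Date, without re-parsing an origin string
.as_date <- function(x) structure(as.numeric(x), class = "Date")

## bottle status codes (stored as integers for fast inventory updates)
.ST_GENERATED <- 1L; .ST_IN_STOCK <- 2L; .ST_DISPENSED <- 3L
.ST_DISPOSED <- 4L
.ST_LEVELS <- c("generated", "in_stock", "dispensed", "disposed")
.status_chr <- function(s) .ST_LEVELS[s]

## Classed error conditions so that callers (and tests) can distinguish
## domain failures: state, authorization, gating, stockout, expiry,
## validation, lookup.
.err <- function(class, msg, call. = FALSE) {
  stop(structure(
    class = c(paste0("trialops_", class), "trialops_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

.default_config <- function() {
  list(
    month_days           = 31L,   # "62 tablets at 2/day covers one month"
    min_shelf_months     = 12,    # minimum shelf life at delivery
    bottle_tablets       = 62L,
    tablet_mg            = 850,
    runin_tablet_mg      = 500,
    runin_days           = 30L,
    treatment_months     = 36,    # mean treatment duration
    dropout_rate         = 0.032, # annual
    accrual_window_months = 6,
    horizon_months       = 12,
    agreement_lead_days  = 30L,   # order agreed within 30 days
    delivery_lead_days   = 60L,   # supplier delivers within 60 days
    expiry_buffer_days   = 30L,   # order at least 30 d before last expiry
    unit_cost            = 4.00,  # Euro per bottle
    age_cut              = 67     # treatment stratum boundary, inclusive
  )
}

#' Create an empty trial
#'
#' A `trial` is the in-memory representation of one running study: the
#' participant roster with per-participant protocol state, the blinded bottle
#' inventory, batch records, the allocation register, the sealed treatment
#' map, stratification ledgers for both randomizations, and an append-only
#' audit log.  It has reference semantics (it is an environment): operations
#' such as [dispense()] or [transition()] modify it in place and return their
#' result invisibly, so large simulations do not copy the whole state on
#' every event.
#'
#' @param seed integer seed for the trial's private random-number stream
#'   (minimization tie-breaks, arm-alias draw, simulator draws).
#' @param config named list overriding entries of the default configuration:
#'   `month_days` (31), `min_shelf_months` (12), `bottle_tablets` (62),
#'   `tablet_mg` (850), `runin_tablet_mg` (500), `runin_days` (30),
#'   `treatment_months` (36), `dropout_rate` (0.032 per year),
#'   `accrual_window_months` (6), `horizon_months` (12),
#'   `agreement_lead_days` (30), `delivery_lead_days` (60),
#'   `expiry_buffer_days` (30), `unit_cost` (4.00), `age_cut` (67).
#' @return an object of class `trial`.
#' @examples
#' tr <- trial_new(seed = 1)
#' register_participant(tr, "P001", "female", "1960-05-01",
#'                      consent_date = "2015-04-01")
#' trial_participants(tr)
#' @export
trial_new <- function(seed = 1L, config = list()) {
  cfg <- .default_config()
  unknown <- setdiff(names(config), names(cfg))
  if (length(unknown))
    .err("validation_error", paste0("unknown config field(s): ",
                                    paste(unknown, collapse = ", ")))
  cfg[names(config)] <- config

  tr <- new.env(parent = emptyenv())
  tr$config <- cfg

  ## participant roster (parallel vectors; see trial_participants())
  tr$p_id        <- character(0)
  tr$p_sex       <- character(0)
  tr$p_birth     <- numeric(0)
  tr$p_family    <- character(0)
  tr$p_proband   <- logical(0)
  tr$p_consent   <- numeric(0)
  tr$p_state     <- character(0)
  tr$p_arm       <- character(0)   # diet arm: blue/green
  tr$p_label     <- character(0)   # blinded treatment label: X/Y
  tr$p_dose      <- character(0)   # full/half
  tr$p_regcomplete <- logical(0)   # registration data complete
  tr$p_eligible  <- logical(0)     # screening outcome (NA until screened)
  tr$p_runin_start <- numeric(0)
  tr$p_runin_ae  <- logical(0)
  tr$p_rand_date <- numeric(0)     # treatment randomization date
  tr$p_trt_end   <- numeric(0)     # scheduled end of treatment
  tr$p_next_due  <- numeric(0)     # next scheduled dispensation
  tr$p_anniv     <- numeric(0)     # first annual visit

  ## blinded bottle inventory
  tr$b_code   <- character(0)
  tr$b_block  <- integer(0)
  tr$b_pos    <- integer(0)
  tr$b_label  <- character(0)
  tr$b_status <- integer(0)        # .ST_* codes
  tr$b_batch  <- character(0)
  tr$b_expiry <- numeric(0)
  tr$fefo      <- list()           # per-label indices sorted by expiry
  tr$fefo_head <- list()           # per-label consumed-prefix pointer

  ## batches
  tr$k_id     <- character(0)
  tr$k_order  <- character(0)
  tr$k_load   <- numeric(0)
  tr$k_expiry <- numeric(0)
  tr$k_n      <- integer(0)

  ## allocation register (one record per blinded dispensation, appended as
  ## env bindings for O(1) growth; see allocation_register())
  tr$reg_n   <- 0L
  tr$reg_env <- new.env(parent = emptyenv(), hash = TRUE)

  ## append-only audit log.  Events live as individual bindings in a hashed
  ## environment so appends are O(1); trial_audit() assembles the data frame.
  tr$au_n   <- 0L
  tr$au_env <- new.env(parent = emptyenv(), hash = TRUE)
  tr$rand_times <- numeric(0)   # treatment-randomization dates (accrual trend)

  ## stratification ledgers
  arms <- c("blue", "green"); labels <- c("X", "Y"); sexes <- c("male", "female")
  tr$led_diet    <- matrix(0L, 2, 2, dimnames = list(arms, sexes))
  tr$led_trt_sex <- matrix(0L, 2, 2, dimnames = list(labels, sexes))
  tr$led_trt_age <- matrix(0L, 2, 2, dimnames = list(labels, c("le67", "gt67")))

  tr$sealed      <- NULL
  tr$n_unseal    <- 0L
  tr$runin_stock <- 0L
  tr$runin_dispensed <- 0L

  ## private RNG stream
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  set.seed(as.integer(seed))
  tr$seed <- as.integer(seed)
  tr$rng_state <- get(".Random.seed", globalenv())
  if (!is.null(old)) assign(".Random.seed", old, globalenv())

  class(tr) <- c("trial", "environment")
  tr
}

## Evaluate `expr` under the trial's private RNG stream, saving the advanced
## state back and restoring the caller's stream.
.with_rng <- function(tr, expr) {
  had <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", globalenv()) else NULL
  assign(".Random.seed", tr$rng_state, globalenv())
  on.exit({
    tr$rng_state <- get(".Random.seed", globalenv())
    if (had) assign(".Random.seed", old, globalenv())
    else rm(".Random.seed", envir = globalenv())
  })
  expr
}

## ---- audit log ----

.audit <- function(tr, date, actor, role, action, subject, payload = "") {
  n <- tr$au_n + 1L
  assign(as.character(n),
         c(time = .day(date), actor = actor, role = role, action = action,
           subject = subject, payload = payload),
         envir = tr$au_env)
  tr$au_n <- n
  invisible(n)
}

## ---- accessors ----

#' Participant roster as a data frame
#'
#' @param tr a [trial_new()] object.
#' @return data frame with one row per registered participant: identifiers,
#'   demographics, family link, protocol state, diet arm, blinded treatment
#'   label, dose level and scheduling dates.  Treatment names never appear.
#' @export
trial_participants <- function(tr) {
  stopifnot(inherits(tr, "trial"))
  data.frame(
    participant_id = tr$p_id, sex = tr$p_sex,
    birth_date = .as_date(tr$p_birth),
    family_id = tr$p_family, is_proband = tr$p_proband,
    consent_date = .as_date(tr$p_consent),
    state = tr$p_state, diet_arm = tr$p_arm,
    treatment_label = tr$p_label, dose_level = tr$p_dose,
    eligible = tr$p_eligible,
    randomized_date = .as_date(tr$p_rand_date),
    treatment_end = .as_date(tr$p_trt_end),
    next_due = .as_date(tr$p_next_due),
    anniversary_date = .as_date(tr$p_anniv),
    stringsAsFactors = FALSE
  )
}

#' Bottle inventory as a data frame
#'
#' Operational view of the blinded stock: each bottle carries its code,
#' block, blinded label (X/Y), status and, once loaded, batch and expiry.
#' The actual treatment is only reachable through [break_blind()].
#'
#' @param tr a [trial_new()] object.
#' @return data frame with one row per generated bottle code.
#' @export
trial_bottles <- function(tr) {
  stopifnot(inherits(tr, "trial"))
  data.frame(
    code = tr$b_code, block_id = tr$b_block, position = tr$b_pos,
    blinded_treatment = tr$b_label, status = .status_chr(tr$b_status),
    batch_id = tr$b_batch, expiry_date = .as_date(tr$b_expiry),
    stringsAsFactors = FALSE
  )
}

#' Batch (delivery lot) records as a data frame
#' @param tr a [trial_new()] object.
#' @return data frame of loaded batches.
#' @export
trial_batches <- function(tr) {
  stopifnot(inherits(tr, "trial"))
  data.frame(
    batch_id = tr$k_id, order_id = tr$k_order,
    load_date = .as_date(tr$k_load), expiry_date = .as_date(tr$k_expiry),
    n_bottles = tr$k_n, stringsAsFactors = FALSE
  )
}

#' Audit log as a data frame
#'
#' Every state transition, dispensation, batch load, order and unblinding
#' appends exactly one event; the log is append-only.
#'
#' @param tr a [trial_new()] object.
#' @return data frame of audit events in append order.
#' @export
trial_audit <- function(tr) {
  stopifnot(inherits(tr, "trial"))
  n <- tr$au_n
  if (n == 0L)
    return(data.frame(date = .as_date(numeric(0)), actor = character(0),
                      actor_role = character(0), action = character(0),
                      subject = character(0), payload = character(0),
                      stringsAsFactors = FALSE))
  ev <- mget(as.character(seq_len(n)), envir = tr$au_env)
  m <- matrix(unlist(ev, use.names = FALSE), ncol = 6L, byrow = TRUE)
  data.frame(
    date = .as_date(as.numeric(m[, 1])), actor = m[, 2],
    actor_role = m[, 3], action = m[, 4],
    subject = m[, 5], payload = m[, 6],
    stringsAsFactors = FALSE
  )
}

#' Trial configuration
#' @param tr a [trial_new()] object.
#' @return named list of configuration values.
#' @export
trial_config <- function(tr) {
  stopifnot(inherits(tr, "trial"))
  tr$config
}

.pidx <- function(tr, id) {
  i <- match(id, tr$p_id)
  if (is.na(i)) .err("lookup_error", paste0("unknown participant: ", id))
  i
}

#' @export
print.trial <- function(x, ...) {
  cat("<trial> seed", x$seed, "\n")
  cat("  participants:", length(x$p_id))
  if (length(x$p_id)) {
    st <- table(x$p_state)
    cat(" (", paste(names(st), st, sep = "=", collapse = ", "), ")", sep = "")
  }
  cat("\n  bottles:", length(x$b_code))
  if (length(x$b_code)) {
    st <- table(.status_chr(x$b_status))
    cat(" (", paste(names(st), st, sep = "=", collapse = ", "), ")", sep = "")
  }
  cat("\n  batches:", length(x$k_id),
      " dispensations:", x$reg_n,
      " audit events:", x$au_n, "\n")
  invisible(x)
}

#' @export
summary.trial <- function(object, ...) {
  out <- list(
    n_participants = length(object$p_id),
    states = table(object$p_state),
    bottle_status = table(.status_chr(object$b_status)),
    n_dispensations = object$reg_n,
    bottles_dispensed = sum(object$b_status == .ST_DISPENSED),
    runin_units_dispensed = object$runin_dispensed,
    n_audit_events = object$au_n
  )
  class(out) <- "summary.trial"
  out
}

#' @export
print.summary.trial <- function(x, ...) {
  cat("Trial summary\n")
  cat("  participants:", x$n_participants, "\n")
  if (length(x$states)) print(x$states)
  if (length(x$bottle_status)) print(x$bottle_status)
  cat("  blinded dispensations:", x$n_dispensations,
      "(", x$bottles_dispensed, "bottles )\n")
  cat("  run-in units dispensed:", x$runin_units_dispensed, "\n")
  cat("  audit events:", x$n_audit_events, "\n")
  invisible(x)
}
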