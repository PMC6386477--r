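#' Per-step medication supply
#'
#' The protocol's medication schedule, one bottle = 62 tablets:
#' `SUPPLY_STEP_1` — 1 bottle, one 850 mg tablet/day, 62 days;
#' `SUPPLY_STEP_2` — 1 bottle, two tablets/day (1700 mg/day), 31 days;
#' `MAINTENANCE` — six-month supply: 6 bottles at full dose (2 tablets/day,
#' 186 days) or 3 bottles at half dose (1 tablet/day, 186 days);
#' `RUN_IN` — one open-label 30-tablet 500 mg unit, 30 days.
#'
#' @param step one of `"RUN_IN"`, `"SUPPLY_STEP_1"`, `"SUPPLY_STEP_2"`,
#'   `"MAINTENANCE"`.
#' @param dose_level `"full"` or `"half"` (used at maintenance).
#' @return list with `bottles`, `days` covered and `tablets_per_day`.
#' @examples
#' required_supply("MAINTENANCE", "full")   # 6 bottles, 186 days
#' required_supply("MAINTENANCE", "half")   # 3 bottles, 186 days
#' @export
required_supply <- function(step, dose_level = "full") {
  if (!dose_level %in% c("full", "half"))
    .err("validation_error", "dose_level must be 'full' or 'half'")
  switch(step,
    RUN_IN        = list(bottles = 1L, days = 30L, tablets_per_day = 1L),
    SUPPLY_STEP_1 = list(bottles = 1L, days = 62L, tablets_per_day = 1L),
    SUPPLY_STEP_2 = list(bottles = 1L, days = 31L, tablets_per_day = 2L),
    MAINTENANCE   = if (dose_level == "full")
                      list(bottles = 6L, days = 186L, tablets_per_day = 2L)
                    else
                      list(bottles = 3L, days = 186L, tablets_per_day = 1L),
    .err("validation_error", paste0("unknown supply step: ", step))
  )
}

## The supply step the next dispensation serves, given the current state.
.next_step <- function(state) {
  switch(state,
         TREATMENT_RANDOMIZED = "SUPPLY_STEP_1",
         SUPPLY_STEP_1        = "SUPPLY_STEP_2",
         SUPPLY_STEP_2        = "MAINTENANCE",
         MAINTENANCE          = "MAINTENANCE",
         NA_character_)
}

.step_event <- c(SUPPLY_STEP_1 = "dispense_step1",
                 SUPPLY_STEP_2 = "dispense_step2",
                 MAINTENANCE   = "dispense_maintenance")

#' Load a delivered batch into the virtual warehouse
#'
#' Registers a delivery lot: quantity, batch number, loading date and
#' expiry date.  Deliveries with a shelf life at loading below the
#' configured minimum (default twelve months) are rejected.  Contained
#' bottle codes move from `generated` to `in_stock`.
#'
#' @param tr a [trial_new()] object.
#' @param batch_id batch number.
#' @param order_id source order identifier.
#' @param load_date,expiry_date dates.
#' @param codes bottle codes contained in the lot (must be `generated`).
#' @param actor,role audit attribution.
#' @return invisibly, a list describing the batch.
#' @export
load_batch <- function(tr, batch_id, order_id, load_date, expiry_date,
                       codes, actor = "pharmacy", role = "pharmacist") {
  stopifnot(inherits(tr, "trial"))
  ld <- .day(load_date); ex <- .day(expiry_date)
  if (is.na(ld) || is.na(ex) || ex <= ld)
    .err("validation_error", "expiry_date must be after load_date")
  min_days <- tr$config$min_shelf_months * tr$config$month_days
  if (ex - ld < min_days)
    .err("validation_error",
         paste0("delivery rejected: shelf life at loading is ", ex - ld,
                " days, below the required ", tr$config$min_shelf_months,
                " months (", min_days, " days)"))
  if (batch_id %in% tr$k_id)
    .err("validation_error", paste0("duplicate batch id: ", batch_id))
  j <- match(codes, tr$b_code)
  if (anyNA(j))
    .err("lookup_error",
         paste0("unknown bottle code(s): ",
                paste(utils::head(codes[is.na(j)], 3), collapse = ", ")))
  bad <- tr$b_status[j] != .ST_GENERATED
  if (any(bad))
    .err("state_error",
         paste0("bottle(s) already loaded: ",
                paste(utils::head(codes[bad], 3), collapse = ", ")))
  tr$b_status[j] <- .ST_IN_STOCK
  tr$b_batch[j]  <- batch_id
  tr$b_expiry[j] <- ex
  for (lab in c("X", "Y")) {
    jl <- j[tr$b_label[j] == lab]
    if (length(jl)) {
      ## drop the consumed prefix, merge the new lot, re-sort by expiry
      old <- tr$fefo[[lab]]
      h <- tr$fefo_head[[lab]]
      keep <- if (h <= length(old)) old[h:length(old)] else integer(0)
      q <- c(keep, jl)
      tr$fefo[[lab]] <- q[order(tr$b_expiry[q])]
      tr$fefo_head[[lab]] <- 1L
    }
  }
  n <- length(tr$k_id) + 1L
  tr$k_id[n] <- batch_id; tr$k_order[n] <- order_id
  tr$k_load[n] <- ld; tr$k_expiry[n] <- ex; tr$k_n[n] <- length(codes)
  .audit(tr, load_date, actor, role, "load_batch", batch_id,
         paste0("order=", order_id, ";n=", length(codes),
                ";expiry=", format(.as_date(ex))))
  invisible(list(batch_id = batch_id, order_id = order_id,
                 load_date = .as_date(ld), expiry_date = .as_date(ex),
                 n_bottles = length(codes)))
}

#' Add open-label run-in stock
#'
#' The 30-tablet 500 mg run-in units form a separate open-label product
#' line tracked as a simple unit count; they never enter the blinded block
#' list.
#'
#' @param tr a [trial_new()] object.
#' @param units number of 30-tablet units.
#' @param date audit date.
#' @return new stock level, invisibly.
#' @export
add_runin_stock <- function(tr, units, date = Sys.Date()) {
  stopifnot(inherits(tr, "trial"), units >= 0)
  tr$runin_stock <- tr$runin_stock + as.integer(units)
  .audit(tr, date, "pharmacy", "pharmacist", "load_runin_stock", "run_in",
         paste0("units=", as.integer(units)))
  invisible(tr$runin_stock)
}

#' Dispense a run-in unit
#'
#' @param tr a [trial_new()] object.
#' @param id participant identifier (state must be `RUN_IN`).
#' @param date dispensation date.
#' @return invisibly, the remaining run-in stock.
#' @export
dispense_run_in <- function(tr, id, date) {
  stopifnot(inherits(tr, "trial"))
  i <- .pidx(tr, id)
  if (tr$p_state[i] != "RUN_IN")
    .err("state_error",
         paste0("run-in dispensation requires state RUN_IN (", id, " is ",
                tr$p_state[i], ")"))
  if (tr$runin_stock < 1L)
    .err("stockout_error", "stockout: no run-in units in stock")
  tr$runin_stock <- tr$runin_stock - 1L
  tr$runin_dispensed <- tr$runin_dispensed + 1L
  .audit(tr, date, "pharmacy", "pharmacist", "dispense_run_in", id, "units=1")
  invisible(tr$runin_stock)
}

#' Dispense the next blinded supply to a participant
#'
#' Determines the step from the participant's state, selects the required
#' bottles among in-stock bottles of the participant's blinded label by
#' FEFO (earliest expiry first), refusing any bottle that would expire
#' before the end of the covered period, marks them dispensed, appends an
#' allocation-register row with the next due date, and advances the state.
#'
#' Distinct failures: participants whose state forbids supply raise a state
#' error; insufficient stock of the label raises a stockout error; stock
#' that exists but is too close to expiry raises an expiry error.
#'
#' @param tr a [trial_new()] object.
#' @param id participant identifier.
#' @param date dispensation date.
#' @param actor,role audit attribution.
#' @return a `dispensation` list: participant, date, step, bottle codes,
#'   tablets per day, days covered, next due date.
#' @export
dispense <- function(tr, id, date, actor = "pharmacy", role = "pharmacist") {
  stopifnot(inherits(tr, "trial"))
  i <- .pidx(tr, id)
  state <- tr$p_state[i]
  step <- .next_step(state)
  if (is.na(step))
    .err("state_error",
         paste0("cannot dispense to ", id, " in state ", state))
  d <- .day(date)
  lab <- tr$p_label[i]
  rs <- required_supply(step, tr$p_dose[i])

  ## FEFO scan: the queue is sorted by expiry; advance from the head past
  ## consumed bottles, skipping in-stock bottles that fail the expiry guard
  ## (they stay for shorter requests or eventual disposal).
  q <- tr$fefo[[lab]]
  h <- tr$fefo_head[[lab]]
  guard <- d + rs$days
  take <- integer(rs$bottles)
  got <- 0L
  short_dated <- 0L
  j <- h
  while (got < rs$bottles && j <= length(q)) {
    bi <- q[j]
    if (tr$b_status[bi] == .ST_IN_STOCK) {
      if (tr$b_expiry[bi] >= guard) {
        got <- got + 1L
        take[got] <- bi
      } else short_dated <- short_dated + 1L
    } else if (j == h) {
      h <- h + 1L                               # amortized prefix advance
    }
    j <- j + 1L
  }
  tr$fefo_head[[lab]] <- h
  if (got < rs$bottles) {
    n_stock <- got + short_dated
    if (n_stock < rs$bottles)
      .err("stockout_error",
           paste0("stockout: ", n_stock, " bottle(s) of label ", lab,
                  " in stock, ", rs$bottles, " required"))
    .err("expiry_error",
         paste0("expiry guard: only ", got, " bottle(s) of label ", lab,
                " survive past the ", rs$days, "-day coverage window (",
                rs$bottles, " required)"))
  }
  tr$b_status[take] <- .ST_DISPENSED

  transition(tr, id, .step_event[[step]], date, actor, role)
  next_due <- d + rs$days
  tr$p_next_due[i] <- next_due

  codes_str <- paste(tr$b_code[take], collapse = ",")
  n <- tr$reg_n + 1L
  assign(as.character(n),
         list(pid = id, date = d, step = step, n = rs$bottles,
              codes = codes_str, expiries = tr$b_expiry[take],
              tpd = rs$tablets_per_day, days = rs$days, nxt = next_due),
         envir = tr$reg_env)
  tr$reg_n <- n
  .audit(tr, date, actor, role, "dispense", id,
         paste0("step=", step, ";n=", rs$bottles, ";codes=", codes_str))
  structure(list(participant_id = id, date = .as_date(d), step = step,
                 bottles = tr$b_code[take],
                 tablets_per_day = rs$tablets_per_day,
                 days_covered = rs$days, next_due = .as_date(next_due)),
            class = "dispensation")
}

#' @export
print.dispensation <- function(x, ...) {
  cat("dispensation:", x$participant_id, format(x$date), "|", x$step, "|",
      length(x$bottles), "bottle(s) |", x$tablets_per_day, "tab/day for",
      x$days_covered, "days | next due", format(x$next_due), "\n")
  invisible(x)
}

#' Dispose of expired stock
#'
#' Every in-stock bottle whose expiry date precedes `today` is marked
#' disposed; disposed bottles can never be dispensed.
#'
#' @param tr a [trial_new()] object.
#' @param today date.
#' @return character vector of disposed bottle codes (possibly empty).
#' @export
dispose_expired <- function(tr, today) {
  stopifnot(inherits(tr, "trial"))
  d <- .day(today)
  idx <- which(tr$b_status == .ST_IN_STOCK & tr$b_expiry < d)
  if (length(idx)) {
    tr$b_status[idx] <- .ST_DISPOSED
    .audit(tr, today, "pharmacy", "pharmacist", "dispose_expired", "stock",
           paste0("n=", length(idx), ";codes=",
                  paste(tr$b_code[idx], collapse = ",")))
  }
  tr$b_code[idx]
}

#' The allocation register
#'
#' Per participant, every dispensation with its date, bottle codes, bottle
#' expiry dates and the next scheduled delivery date.  Treatment names
#' never appear (bottles are identified by code and blinded label only).
#'
#' @param tr a [trial_new()] object.
#' @return data frame, one row per dispensation.
#' @export
allocation_register <- function(tr) {
  stopifnot(inherits(tr, "trial"))
  n <- tr$reg_n
  if (n == 0L)
    return(data.frame(participant_id = character(0),
                      date = .as_date(numeric(0)), step = character(0),
                      n_bottles = integer(0), bottle_codes = character(0),
                      expiry_dates = character(0),
                      tablets_per_day = integer(0),
                      days_covered = integer(0),
                      next_due = .as_date(numeric(0)),
                      stringsAsFactors = FALSE))
  recs <- mget(as.character(seq_len(n)), envir = tr$reg_env)
  data.frame(
    participant_id = vapply(recs, `[[`, "", "pid"),
    date = .as_date(vapply(recs, `[[`, 0, "date")),
    step = vapply(recs, `[[`, "", "step"),
    n_bottles = vapply(recs, function(r) as.integer(r$n), 0L),
    bottle_codes = vapply(recs, `[[`, "", "codes"),
    expiry_dates = vapply(recs, function(r)
      paste(format(.as_date(r$expiries)), collapse = ","), ""),
    tablets_per_day = vapply(recs, function(r) as.integer(r$tpd), 0L),
    days_covered = vapply(recs, function(r) as.integer(r$days), 0L),
    next_due = .as_date(vapply(recs, `[[`, 0, "nxt")),
    stringsAsFactors = FALSE, row.names = NULL
  )
}

#' Stock report by label, batch and status
#'
#' @param tr a [trial_new()] object.
#' @return data frame of bottle counts.
#' @export
stock_report <- function(tr) {
  stopifnot(inherits(tr, "trial"))
  b <- trial_bottles(tr)
  out <- as.data.frame(table(label = b$blinded_treatment,
                             batch = ifelse(is.na(b$batch_id), "(unloaded)",
                                            b$batch_id),
                             status = b$status),
                       stringsAsFactors = FALSE)
  names(out)[4] <- "n"
  out[out$n > 0, , drop = FALSE]
}
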