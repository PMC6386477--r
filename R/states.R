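#' Protocol states
#'
#' The participant life cycle: registration, diet randomization, the 30-day
#' open-label 500 mg run-in, treatment randomization, the two single-bottle
#' supply steps (one 850 mg tablet/day for two months, then two tablets —
#' 1700 mg/day — for one month), six-monthly maintenance supplies, and the
#' terminal/blocking states.
#'
#' @return character vector of all state names.
#' @export
participant_states <- function() {
  c("REGISTERED", "DIET_RANDOMIZED", "RUN_IN", "SCREEN_FAILED",
    "TREATMENT_RANDOMIZED", "SUPPLY_STEP_1", "SUPPLY_STEP_2",
    "MAINTENANCE", "BLOCKED", "WITHDRAWN", "COMPLETED")
}

#' Protocol events
#' @return character vector of all event names accepted by [transition()].
#' @export
trial_events <- function() {
  c("diet_randomize", "start_run_in", "screen_fail", "run_in_adverse_event",
    "treatment_randomize", "dispense_step1", "dispense_step2",
    "dispense_maintenance", "complete", "non_compliance",
    "serious_adverse_event", "consent_withdrawal")
}

.terminal_states <- c("SCREEN_FAILED", "WITHDRAWN", "COMPLETED")

## States from which non-compliance / SAE block the participant.  BLOCKED
## itself only admits consent withdrawal.
.blockable_states <- c("REGISTERED", "DIET_RANDOMIZED", "RUN_IN",
                       "TREATMENT_RANDOMIZED", "SUPPLY_STEP_1",
                       "SUPPLY_STEP_2", "MAINTENANCE")

#' The declared transition table
#'
#' @return data frame with columns `from`, `event`, `to` enumerating every
#'   legal transition; any (state, event) pair not listed is illegal.
#' @export
transition_table <- function() {
  flow <- rbind(
    c("REGISTERED",           "diet_randomize",        "DIET_RANDOMIZED"),
    c("DIET_RANDOMIZED",      "screen_fail",           "SCREEN_FAILED"),
    c("DIET_RANDOMIZED",      "start_run_in",          "RUN_IN"),
    c("RUN_IN",               "screen_fail",           "SCREEN_FAILED"),
    c("RUN_IN",               "run_in_adverse_event",  "SCREEN_FAILED"),
    c("RUN_IN",               "treatment_randomize",   "TREATMENT_RANDOMIZED"),
    c("TREATMENT_RANDOMIZED", "dispense_step1",        "SUPPLY_STEP_1"),
    c("SUPPLY_STEP_1",        "dispense_step2",        "SUPPLY_STEP_2"),
    c("SUPPLY_STEP_2",        "dispense_maintenance",  "MAINTENANCE"),
    c("MAINTENANCE",          "dispense_maintenance",  "MAINTENANCE"),
    c("MAINTENANCE",          "complete",              "COMPLETED")
  )
  block <- cbind(rep(.blockable_states, 2),
                 rep(c("non_compliance", "serious_adverse_event"),
                     each = length(.blockable_states)),
                 "BLOCKED")
  withdraw <- cbind(c(.blockable_states, "BLOCKED"),
                    "consent_withdrawal", "WITHDRAWN")
  tab <- rbind(flow, block, withdraw)
  data.frame(from = tab[, 1], event = tab[, 2], to = tab[, 3],
             stringsAsFactors = FALSE)
}

## cached lookup: named vector "from|event" -> to
.transition_map <- local({
  map <- NULL
  function() {
    if (is.null(map)) {
      tab <- transition_table()
      map <<- stats::setNames(tab$to, paste(tab$from, tab$event, sep = "|"))
    }
    map
  }
})

.next_state <- function(from, event) {
  to <- .transition_map()[paste(from, event, sep = "|")]
  unname(to)
}

#' Apply a protocol event to a participant
#'
#' The state machine gates every other module: dispensing, randomization and
#' supply all refuse participants whose state does not admit the operation.
#' Blocking events (`non_compliance`, `serious_adverse_event`) and consent
#' withdrawal are accepted from any active state; `WITHDRAWN`, `COMPLETED`
#' and `SCREEN_FAILED` are terminal.
#'
#' @param tr a [trial_new()] object.
#' @param id participant identifier.
#' @param event one of [trial_events()].
#' @param date event date.
#' @param actor,role audit attribution (default the data manager).
#' @return the new state, invisibly; exactly one audit event is appended.
#' @export
transition <- function(tr, id, event, date,
                       actor = "system", role = "data_manager") {
  stopifnot(inherits(tr, "trial"))
  if (!event %in% trial_events())
    .err("validation_error", paste0("unknown event: ", event))
  i <- .pidx(tr, id)
  from <- tr$p_state[i]
  to <- .next_state(from, event)
  if (is.na(to))
    .err("state_error", paste0("illegal transition: event '", event,
                               "' from state '", from, "' for ", id))
  tr$p_state[i] <- to
  if (event == "start_run_in") tr$p_runin_start[i] <- .day(date)
  if (event == "run_in_adverse_event") tr$p_runin_ae[i] <- TRUE
  .audit(tr, date, actor, role, "transition", id,
         paste(event, from, to, sep = "|"))
  invisible(to)
}

#' Adjust a participant's dose level
#'
#' Only the principal investigator may reduce a participant to a half dose
#' (or restore the full dose), e.g. for poor metformin tolerance or
#' regression of the metabolic disorder.  Subsequent supply computations use
#' the new level (3 instead of 6 bottles per maintenance cycle).
#'
#' @param tr a [trial_new()] object.
#' @param id participant identifier.
#' @param level `"full"` or `"half"`.
#' @param actor actor identifier.
#' @param role actor role; must be `"PI"`.
#' @param date event date.
#' @return the new level, invisibly.
#' @export
set_dose <- function(tr, id, level, actor, role, date = Sys.Date()) {
  stopifnot(inherits(tr, "trial"))
  if (!level %in% c("full", "half"))
    .err("validation_error", "dose level must be 'full' or 'half'")
  if (!identical(role, "PI"))
    .err("auth_error", "authorization error: only the PI may adjust the dose")
  i <- .pidx(tr, id)
  if (is.na(tr$p_label[i]))
    .err("state_error",
         paste0("dose can only be set after treatment randomization (", id,
                " is ", tr$p_state[i], ")"))
  tr$p_dose[i] <- level
  .audit(tr, date, actor, role, "set_dose", id, paste0("level=", level))
  invisible(level)
}
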