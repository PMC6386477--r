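#' Reconstruct participant states from the audit log
#'
#' Event-sourcing round trip: replays every `transition` audit event in
#' order and returns the resulting state per participant (participants with
#' no transition yet are `REGISTERED`).
#'
#' @param tr a [trial_new()] object.
#' @return named character vector, participant id -> state.
#' @export
replay_states <- function(tr) {
  stopifnot(inherits(tr, "trial"))
  st <- stats::setNames(rep("REGISTERED", length(tr$p_id)), tr$p_id)
  au <- trial_audit(tr)
  is_tr <- au$action == "transition"
  subj <- au$subject[is_tr]
  to <- vapply(strsplit(au$payload[is_tr], "|", fixed = TRUE),
               `[`, character(1), 3L)
  for (k in seq_along(subj)) st[subj[k]] <- to[k]
  st
}

#' Check that the audit log reconstructs the live state
#'
#' @param tr a [trial_new()] object.
#' @return `TRUE` if replaying the audit log yields exactly the current
#'   state of every participant, else `FALSE` with a `mismatches`
#'   attribute.
#' @export
audit_replay_ok <- function(tr) {
  st <- replay_states(tr)
  live <- stats::setNames(tr$p_state, tr$p_id)
  ok <- identical(unname(st[names(live)]), unname(live))
  if (!ok)
    attr(ok, "mismatches") <- names(live)[st[names(live)] != live]
  ok
}

#' Inventory conservation check
#'
#' Every generated bottle is, at all times, in exactly one of the states
#' generated / in_stock / dispensed / disposed.
#'
#' @param tr a [trial_new()] object.
#' @return `TRUE` or `FALSE`.
#' @export
inventory_conservation <- function(tr) {
  stopifnot(inherits(tr, "trial"))
  all(tr$b_status %in% c(.ST_GENERATED, .ST_IN_STOCK, .ST_DISPENSED,
                         .ST_DISPOSED)) &&
    length(tr$b_status) == length(tr$b_code)
}

#' Blind-integrity string scan
#'
#' Serializes every operational output — the participant roster, bottle
#' table, batch table, allocation register, stock report, balance report
#' and the audit log (with unblinding payloads redacted, as those are the
#' one sanctioned leak) — and counts occurrences of treatment names.  A
#' blinded system must return zero.
#'
#' @param tr a [trial_new()] object.
#' @return integer count of treatment-name occurrences (0 when blind).
#' @export
blind_scan <- function(tr) {
  stopifnot(inherits(tr, "trial"))
  au <- trial_audit(tr)
  au$payload[au$action == "break_blind"] <- "[redacted]"
  texts <- c(
    utils::capture.output(utils::write.csv(trial_participants(tr), stdout())),
    utils::capture.output(utils::write.csv(trial_bottles(tr), stdout())),
    utils::capture.output(utils::write.csv(trial_batches(tr), stdout())),
    utils::capture.output(utils::write.csv(allocation_register(tr),
                                           stdout())),
    utils::capture.output(utils::write.csv(stock_report(tr), stdout())),
    utils::capture.output(print(balance_report(tr))),
    utils::capture.output(utils::write.csv(au, stdout()))
  )
  sum(grepl("metformin|placebo", texts, ignore.case = TRUE))
}
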