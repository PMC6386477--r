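## Bottles scheduled for participant i strictly after `from` and up to `to`
## (both numeric days), walking the protocol schedule from the current state
## and next-due date at the participant's current dose, stopping at the
## scheduled treatment end.
.bottles_due <- function(tr, i, from, to) {
  state <- tr$p_state[i]
  step <- .next_step(state)
  if (is.na(step)) return(0L)
  d <- tr$p_next_due[i]
  end <- tr$p_trt_end[i]
  dose <- tr$p_dose[i]
  total <- 0L
  while (!is.na(d) && d <= to && d < end) {
    rs <- required_supply(step, dose)
    if (d > from) total <- total + rs$bottles
    d <- d + rs$days
    state <- switch(step, SUPPLY_STEP_1 = "SUPPLY_STEP_1",
                    SUPPLY_STEP_2 = "SUPPLY_STEP_2",
                    MAINTENANCE = "MAINTENANCE")
    step <- .next_step(state)
  }
  total
}

## Bottles a newly randomized full-dose participant needs in their first
## `months` of treatment, from the schedule itself.
.first_period_bottles <- function(months, month_days = 31L) {
  horizon <- months * month_days
  d <- 0; step <- "SUPPLY_STEP_1"; total <- 0L
  while (d < horizon) {
    rs <- required_supply(step, "full")
    total <- total + rs$bottles
    d <- d + rs$days
    step <- switch(step, SUPPLY_STEP_1 = "SUPPLY_STEP_2",
                   SUPPLY_STEP_2 = "MAINTENANCE", MAINTENANCE = "MAINTENANCE")
  }
  total
}

#' Estimate the next drug order: (A + B1 + B2) - C
#'
#' The order placed with the pharmaceutical company is built from four
#' components: `A`, bottles scheduled for already-randomized active
#' participants within the horizon; `B1`, bottles for projected future
#' randomizations, from the mean monthly treatment-randomization rate over
#' a trailing accrual window times the first-year bottle need per
#' participant; `B2`, run-in units for participants currently between
#' baseline screening and randomization; and `C`, bottles not needed
#' because of estimated withdrawals, taken as the drop-out rate applied to
#' `A + B1`.  The total is exactly `(A + B1 + B2) - C`.
#'
#' @param tr a [trial_new()] object.
#' @param today estimation date.
#' @param horizon_months forecast horizon (default from config, 12 months).
#' @param accrual_window_months trailing window for the recruitment trend
#'   (default from config, 6 months).
#' @param dropout_rate estimated withdrawal fraction applied to `A + B1`
#'   (default from config, 0.032).
#' @return an `order_estimate`: list with `A`, `B1`, `B2`, `C`, `total`,
#'   `horizon_months`, `date`.
#' @export
estimate_order <- function(tr, today,
                           horizon_months = NULL,
                           accrual_window_months = NULL,
                           dropout_rate = NULL) {
  stopifnot(inherits(tr, "trial"))
  cfg <- tr$config
  if (is.null(horizon_months)) horizon_months <- cfg$horizon_months
  if (is.null(accrual_window_months))
    accrual_window_months <- cfg$accrual_window_months
  if (is.null(dropout_rate)) dropout_rate <- cfg$dropout_rate
  if (horizon_months <= 0)
    .err("validation_error", "horizon must be positive")
  d <- .day(today)
  to <- d + horizon_months * cfg$month_days

  active <- which(tr$p_state %in% c("TREATMENT_RANDOMIZED", "SUPPLY_STEP_1",
                                    "SUPPLY_STEP_2", "MAINTENANCE"))
  A <- 0L
  for (i in active) A <- A + .bottles_due(tr, i, d, to)

  rand_times <- tr$rand_times
  win_lo <- d - accrual_window_months * cfg$month_days
  rate <- sum(rand_times > win_lo & rand_times <= d) / accrual_window_months
  B1 <- rate * horizon_months *
    .first_period_bottles(12, cfg$month_days)

  B2 <- sum(tr$p_state == "RUN_IN") * 1L
  C <- dropout_rate * (A + B1)
  structure(list(A = A, B1 = B1, B2 = B2, C = C,
                 total = A + B1 + B2 - C,
                 horizon_months = horizon_months, date = .as_date(d)),
            class = "order_estimate")
}

#' @export
print.order_estimate <- function(x, ...) {
  cat("Order estimate", format(x$date), "| horizon", x$horizon_months,
      "months\n")
  cat(sprintf("  A  (randomized, scheduled)   %10.1f bottles\n", x$A))
  cat(sprintf("  B1 (projected accrual)       %10.1f bottles\n", x$B1))
  cat(sprintf("  B2 (run-in pipeline)         %10.1f units\n", x$B2))
  cat(sprintf("  C  (estimated withdrawals)   %10.1f bottles\n", x$C))
  cat(sprintf("  total (A+B1+B2)-C            %10.1f\n", x$total))
  invisible(x)
}

#' Write an order document
#'
#' @param x an `order_estimate`.
#' @param path CSV output path (a human-readable summary is printed).
#' @return `path`, invisibly.
#' @export
export_order <- function(x, path) {
  stopifnot(inherits(x, "order_estimate"))
  utils::write.csv(data.frame(component = c("A", "B1", "B2", "C", "total"),
                              bottles = c(x$A, x$B1, x$B2, x$C, x$total)),
                   path, row.names = FALSE)
  invisible(path)
}

#' Should an order be placed now?
#'
#' Needs are estimated at least 30 days before the last batches expire
#' (configurable buffer), and an order is also triggered when the scheduled
#' demand within the supplier's delivery lead time (60 days) exceeds the
#' usable stock.
#'
#' @param tr a [trial_new()] object.
#' @param today date.
#' @param lead_days supplier delivery lead time (default from config).
#' @param buffer_days order-before-expiry buffer (default from config).
#' @return list with `order_now` (logical), `latest_order_date`, `reason`.
#' @export
order_trigger <- function(tr, today, lead_days = NULL, buffer_days = NULL) {
  stopifnot(inherits(tr, "trial"))
  cfg <- tr$config
  if (is.null(lead_days)) lead_days <- cfg$delivery_lead_days
  if (is.null(buffer_days)) buffer_days <- cfg$expiry_buffer_days
  d <- .day(today)
  in_stock <- tr$b_status == .ST_IN_STOCK
  if (!any(in_stock))
    return(list(order_now = TRUE, latest_order_date = .as_date(d),
                reason = "no stock"))
  latest_exp <- max(tr$b_expiry[in_stock])
  latest_order <- latest_exp - buffer_days
  if (d >= latest_order)
    return(list(order_now = TRUE, latest_order_date = .as_date(latest_order),
                reason = sprintf("within %d days of last batch expiry",
                                 buffer_days)))
  active <- which(tr$p_state %in% c("TREATMENT_RANDOMIZED", "SUPPLY_STEP_1",
                                    "SUPPLY_STEP_2", "MAINTENANCE"))
  ## project demand over the delivery lead plus the review cadence and the
  ## safety buffer, so an order placed now arrives before the shelf empties
  window <- lead_days + cfg$month_days + buffer_days
  demand <- 0L
  for (i in active) demand <- demand + .bottles_due(tr, i, d, d + window)
  usable <- sum(in_stock & tr$b_expiry >= d)
  if (demand > usable)
    return(list(order_now = TRUE, latest_order_date = .as_date(latest_order),
                reason = sprintf("projected stockout within %d-day lead (demand %d over %d days > stock %d)",
                                 lead_days, demand, window, usable)))
  list(order_now = FALSE, latest_order_date = .as_date(latest_order),
       reason = "stock sufficient")
}

#' Bottles required under a patients'-pack policy
#'
#' The counterfactual baseline: a full multi-year allotment assigned up
#' front to every consented code, at one full-dose bottle per month of mean
#' treatment, discounted only by the expected loss to follow-up.
#'
#' @param n_participants consented cohort size.
#' @param mean_months mean months of treatment per participant.
#' @param loss_rate expected loss to follow-up in `[0, 1)`.
#' @return bottle count, rounded to the nearest integer.
#' @examples
#' patients_pack_requirement(1755, 36, 0.05)  # 60021
#' @export
patients_pack_requirement <- function(n_participants, mean_months,
                                      loss_rate) {
  if (!is.numeric(n_participants) || n_participants <= 0 ||
      !is.numeric(mean_months) || mean_months <= 0)
    .err("validation_error", "n_participants and mean_months must be positive")
  if (!is.numeric(loss_rate) || loss_rate < 0 || loss_rate >= 1)
    .err("validation_error", "loss_rate must be in [0, 1)")
  round(n_participants * mean_months * (1 - loss_rate))
}

#' On-demand vs patients'-pack savings
#'
#' Computes the drug saving of the on-demand supply policy against the
#' patients'-pack counterfactual:
#' `savings_pct = 100 * (theoretical_pp - (dispensed + projected_to_end)) /
#' theoretical_pp`, reported to one decimal; `bottles_saved =
#' theoretical_pp - dispensed - projected_to_end`; the budget saving is
#' `bottles_saved * unit_cost`, reported raw and rounded to the nearest
#' thousand.
#'
#' @param theoretical_pp bottles under the patients'-pack policy (positive).
#' @param dispensed bottles actually dispensed.
#' @param projected_to_end estimated bottles to conclude the study.
#' @param unit_cost currency per bottle (default 4.00).
#' @return a `savings_report` list.
#' @examples
#' savings_report(60021, 11737, 30606, 4.00)
#' @export
savings_report <- function(theoretical_pp, dispensed, projected_to_end,
                           unit_cost = 4.00) {
  if (!is.numeric(theoretical_pp) || theoretical_pp <= 0)
    .err("validation_error",
         "theoretical_pp must be positive (savings percentage undefined)")
  saved <- theoretical_pp - dispensed - projected_to_end
  pct <- round(100 * (theoretical_pp - (dispensed + projected_to_end)) /
                 theoretical_pp, 1)
  budget <- saved * unit_cost
  structure(list(theoretical_pp = theoretical_pp, dispensed = dispensed,
                 projected_to_end = projected_to_end,
                 bottles_saved = saved, savings_pct = pct,
                 unit_cost = unit_cost, budget_saving = budget,
                 budget_saving_rounded = round(budget, -3)),
            class = "savings_report")
}

#' @export
print.savings_report <- function(x, ...) {
  cat("On-demand vs patients'-pack savings\n")
  cat(sprintf("  patients'-pack requirement  %10.0f bottles\n",
              x$theoretical_pp))
  cat(sprintf("  dispensed                   %10.0f bottles\n", x$dispensed))
  cat(sprintf("  projected to end            %10.0f bottles\n",
              x$projected_to_end))
  cat(sprintf("  bottles saved               %10.0f\n", x$bottles_saved))
  cat(sprintf("  savings                     %10.1f %%\n", x$savings_pct))
  cat(sprintf("  budget saving               %10.2f (about %s)\n",
              x$budget_saving,
              format(x$budget_saving_rounded, big.mark = ",")))
  invisible(x)
}
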