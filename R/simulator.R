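#' Simulator configuration
#'
#' Defines the synthetic-trial conditions.  Defaults describe the study the
#' package was built around: accrual open for 40 months at a mean of 44
#' consented volunteers/month (Poisson), a familiar fraction of 0.082 and a
#' female fraction of 0.605 (the recruited cohort's margins), screen-failure
#' and run-in adverse-event probabilities of 0.32 and 0.10 so that about
#' 60% of consented volunteers reach treatment randomization, an annual
#' drop-out rate of 3.2%, 36 months of treatment, a 4.00 Euro bottle and
#' 48-month batch expiries.
#'
#' @param seed integer seed (drives every random draw through the trial's
#'   private stream).
#' @param months months of open accrual.
#' @param accrual_mean mean consented volunteers per month (Poisson).
#' @param familiar_prop probability a new volunteer is a familiar attached
#'   to a uniformly chosen existing family.
#' @param female_prop probability of female sex.
#' @param age_mean,age_sd,age_min,age_max truncated-normal age at consent,
#'   years.
#' @param screen_fail_prob probability of failing the baseline screening.
#' @param runin_ae_prob probability of an adverse event during the 30-day
#'   run-in.
#' @param dropout_rate annual drop-out (consent withdrawal) rate among
#'   randomized participants.
#' @param halfdose_annual_prob annual probability that the PI halves a
#'   maintenance participant's dose.
#' @param treatment_months scheduled treatment duration (>= 4 so the two
#'   supply steps fit inside it).
#' @param screening_delay_days days between registration and the baseline
#'   visit.
#' @param unit_cost Euro per bottle.
#' @param pp_loss loss-to-follow-up fraction used by the patients'-pack
#'   counterfactual.
#' @param batch_expiry_months shelf life of delivered batches.
#' @param n_bottles allocation-list size; `NULL` = sized automatically from
#'   the expected demand (multiple of 4).
#' @param initial_batch_frac fraction of the allocation list loaded as the
#'   first batch at trial start.
#' @param run_months if set, stop the simulation after this many months,
#'   leaving participants mid-flight (useful for interim forecasts);
#'   `NULL` = run until every participant reaches a terminal state.
#' @param start_date first day of the trial.
#' @param key sealing key used for the blinded arm map.
#' @return a `sim_config` list.
#' @export
sim_config <- function(seed = 1L, months = 40, accrual_mean = 44,
                       familiar_prop = 0.082, female_prop = 0.605,
                       age_mean = 56, age_sd = 8, age_min = 40, age_max = 80,
                       screen_fail_prob = 0.32, runin_ae_prob = 0.10,
                       dropout_rate = 0.032, halfdose_annual_prob = 0.05,
                       treatment_months = 36, screening_delay_days = 21,
                       unit_cost = 4.00, pp_loss = 0.05,
                       batch_expiry_months = 48, n_bottles = NULL,
                       initial_batch_frac = 0.35, run_months = NULL,
                       start_date = "2015-04-01", key = "trial-seal-key") {
  cfg <- list(seed = as.integer(seed), months = months,
              accrual_mean = accrual_mean, familiar_prop = familiar_prop,
              female_prop = female_prop, age_mean = age_mean,
              age_sd = age_sd, age_min = age_min, age_max = age_max,
              screen_fail_prob = screen_fail_prob,
              runin_ae_prob = runin_ae_prob, dropout_rate = dropout_rate,
              halfdose_annual_prob = halfdose_annual_prob,
              treatment_months = treatment_months,
              screening_delay_days = screening_delay_days,
              unit_cost = unit_cost, pp_loss = pp_loss,
              batch_expiry_months = batch_expiry_months,
              n_bottles = n_bottles, initial_batch_frac = initial_batch_frac,
              run_months = run_months, start_date = start_date, key = key)
  probs <- c("familiar_prop", "female_prop", "screen_fail_prob",
             "runin_ae_prob", "halfdose_annual_prob", "pp_loss")
  for (p in probs)
    if (!is.numeric(cfg[[p]]) || cfg[[p]] < 0 || cfg[[p]] > 1)
      .err("validation_error", paste0(p, " must be a probability in [0, 1]"))
  if (!is.numeric(cfg$dropout_rate) || cfg$dropout_rate < 0 ||
      cfg$dropout_rate > 1)
    .err("validation_error", "dropout_rate must be in [0, 1]")
  if (!is.numeric(cfg$months) || cfg$months < 1)
    .err("validation_error", "months must be >= 1")
  if (!is.numeric(cfg$treatment_months) || cfg$treatment_months < 4)
    .err("validation_error",
         "treatment_months must be >= 4 (the supply steps cover 3 months)")
  if (!is.numeric(cfg$accrual_mean) || cfg$accrual_mean < 0)
    .err("validation_error", "accrual_mean must be non-negative")
  class(cfg) <- "sim_config"
  cfg
}

## synthetic baseline measures consistent with the intended screening
## outcome; run through the real eligibility functions.
.synth_measures <- function(tr, sex, eligible) {
  if (eligible) {
    baseline_measures(waist_cm = if (sex == "female") 92 else 106,
                      glycemia_mg_dl = 104, triglycerides_mg_dl = 165,
                      hdl_mg_dl = if (sex == "female") 46 else 38,
                      systolic_mmHg = 136, diastolic_mmHg = 82,
                      creatinine_umol_l = 80)
  } else if (.with_rng(tr, stats::runif(1)) < 0.5) {
    # too few metabolic criteria
    baseline_measures(waist_cm = if (sex == "female") 80 else 95,
                      glycemia_mg_dl = 92, triglycerides_mg_dl = 120,
                      hdl_mg_dl = 60, systolic_mmHg = 118,
                      diastolic_mmHg = 76, creatinine_umol_l = 80)
  } else {
    # syndrome present but an exclusion criterion violated
    baseline_measures(waist_cm = if (sex == "female") 92 else 106,
                      glycemia_mg_dl = 104, triglycerides_mg_dl = 165,
                      hdl_mg_dl = if (sex == "female") 46 else 38,
                      systolic_mmHg = 136, diastolic_mmHg = 82,
                      creatinine_umol_l = 130)
  }
}

#' Run a synthetic trial end to end
#'
#' Drives every module with no external data: monthly Poisson accrual with
#' immediate diet randomization, baseline screening through the real
#' eligibility rules, the open-label run-in, treatment randomization by
#' minimization, blinded FEFO dispensations on the protocol schedule,
#' monthly drop-out and dose-reduction hazards, monthly disposal of expired
#' stock, and (A+B1+B2)-C orders triggered by the 30-day expiry / 60-day
#' lead rules.  Time advances in one-day ticks; a month is 31 days.
#' Reproducible from the seed.
#'
#' @param config a [sim_config()].
#' @return a `sim_result`: list with `config`, the final `trial`, `totals`
#'   (aggregated from the audit log), `monthly` event counts, the final
#'   `balance` report and `end_day`.
#' @export
run_simulation <- function(config) {
  if (!inherits(config, "sim_config"))
    .err("validation_error", "config must be a sim_config object")
  cc <- config
  tr <- trial_new(seed = cc$seed,
                  config = list(treatment_months = cc$treatment_months,
                                dropout_rate = cc$dropout_rate,
                                unit_cost = cc$unit_cost))
  start <- .day(cc$start_date)
  month_days <- tr$config$month_days

  exp_consented <- cc$months * cc$accrual_mean
  exp_rand <- exp_consented * (1 - cc$screen_fail_prob) *
    (1 - cc$runin_ae_prob)
  per_completer <- .first_period_bottles(cc$treatment_months, month_days)
  n_bottles <- cc$n_bottles
  if (is.null(n_bottles))
    n_bottles <- max(40L, 4L * ceiling(exp_rand * (per_completer + 4) *
                                         1.35 / 4))
  alloc <- generate_allocation_list(
    n_bottles, seed = as.integer((cc$seed + 104729) %% 2147483647))
  attach_allocation(tr, alloc, cc$key, date = start)
  add_runin_stock(tr, as.integer(ceiling(exp_consented *
                                           (1 - cc$screen_fail_prob) * 1.3)
                                 + 20L),
                  date = start)

  batch_life <- cc$batch_expiry_months * month_days
  n0 <- min(n_bottles, max(40L, 4L * ceiling(n_bottles *
                                               cc$initial_batch_frac / 4)))
  load_batch(tr, "BATCH001", "ORDER000", start,
             start + batch_life, alloc$code[seq_len(n0)])
  loaded_ptr <- n0
  n_batches <- 1L
  n_orders <- 0L
  pending_day <- NA_real_   # relative day of scheduled delivery
  pending_n <- 0L

  sched <- new.env(parent = emptyenv())
  push <- function(rel_day, idx) {
    k <- as.character(rel_day)
    sched[[k]] <- c(sched[[k]], idx)
  }

  p_drop_m <- 1 - (1 - cc$dropout_rate)^(1 / 12)
  p_half_m <- 1 - (1 - cc$halfdose_annual_prob)^(1 / 12)
  dispensing_states <- c("TREATMENT_RANDOMIZED", "SUPPLY_STEP_1",
                         "SUPPLY_STEP_2", "MAINTENANCE")
  nonterminal <- setdiff(participant_states(),
                         c("SCREEN_FAILED", "WITHDRAWN", "COMPLETED"))

  run_limit <- if (!is.null(cc$run_months)) cc$run_months * month_days
               else (cc$months + cc$treatment_months + 10) * month_days
  counter <- 0L

  for (rel in 0:run_limit) {
    day <- start + rel

    if (rel %% month_days == 0) {
      m <- rel %/% month_days

      if (m < cc$months && cc$accrual_mean > 0) {
        n_new <- .with_rng(tr, stats::rpois(1, cc$accrual_mean))
        for (j in seq_len(n_new)) {
          counter <- counter + 1L
          pid <- sprintf("P%05d", counter)
          draws <- .with_rng(tr, stats::runif(2))
          sex <- if (draws[1] < cc$female_prop) "female" else "male"
          fams <- unique(tr$p_family[!is.na(tr$p_family)])
          if (draws[2] < cc$familiar_prop && length(fams)) {
            fam <- fams[.with_rng(tr, sample.int(length(fams), 1))]
          } else {
            fam <- sprintf("F%05d", counter)
          }
          age <- cc$age_mean
          repeat {
            age <- .with_rng(tr, stats::rnorm(1, cc$age_mean, cc$age_sd))
            if (age >= cc$age_min && age <= cc$age_max) break
          }
          birth <- .as_date(day - round(age * 365.25))
          register_participant(tr, pid, sex, birth, day, fam)
          randomize_diet(tr, pid, day)
          push(rel + cc$screening_delay_days, counter)
        }
      }

      if (m > 0) {
        ## monthly drop-out among randomized actives
        act <- which(tr$p_state %in% dispensing_states)
        if (length(act)) {
          u <- .with_rng(tr, stats::runif(length(act)))
          for (i in act[u < p_drop_m])
            transition(tr, tr$p_id[i], "consent_withdrawal", day)
        }
        ## monthly dose reductions among full-dose maintenance participants
        mt <- which(tr$p_state == "MAINTENANCE" & tr$p_dose == "full")
        if (length(mt)) {
          u <- .with_rng(tr, stats::runif(length(mt)))
          for (i in mt[u < p_half_m])
            set_dose(tr, tr$p_id[i], "half", "PI01", "PI", day)
        }
        dispose_expired(tr, day)
        ## ordering
        if (is.na(pending_day) && loaded_ptr < n_bottles) {
          trig <- order_trigger(tr, day)
          if (trig$order_now) {
            est <- estimate_order(tr, day)
            need <- max(40L, 4L * ceiling(max(est$total, 0) / 4))
            n_ord <- min(n_bottles - loaded_ptr, need)
            if (n_ord > 0) {
              n_orders <- n_orders + 1L
              .audit(tr, day, "PI01", "PI", "order",
                     sprintf("ORDER%03d", n_orders),
                     sprintf("A=%.1f;B1=%.1f;B2=%.1f;C=%.1f;total=%.1f;n=%d",
                             est$A, est$B1, est$B2, est$C, est$total, n_ord))
              pending_day <- rel + tr$config$delivery_lead_days
              pending_n <- n_ord
            }
          }
        }
        if (tr$runin_stock < 10L)
          add_runin_stock(tr, max(20L, ceiling(cc$accrual_mean)),
                          day)
        ## early exit once accrual is closed and everyone is terminal
        if (m >= cc$months && is.na(pending_day) &&
            !any(tr$p_state %in% nonterminal))
          break
      }
    }

    if (!is.na(pending_day) && rel >= pending_day) {
      n_batches <- n_batches + 1L
      codes <- tr$b_code[(loaded_ptr + 1):(loaded_ptr + pending_n)]
      load_batch(tr, sprintf("BATCH%03d", n_batches),
                 sprintf("ORDER%03d", n_orders), day,
                 day + batch_life, codes)
      loaded_ptr <- loaded_ptr + pending_n
      pending_day <- NA_real_
    }

    k <- as.character(rel)
    due <- sched[[k]]
    if (!is.null(due)) {
      rm(list = k, envir = sched)
      for (i in due) {
        st <- tr$p_state[i]
        pid <- tr$p_id[i]
        if (st == "DIET_RANDOMIZED") {
          fail <- .with_rng(tr, stats::runif(1)) < cc$screen_fail_prob
          meas <- .synth_measures(tr, tr$p_sex[i], !fail)
          res <- screen_eligibility(meas, tr$p_sex[i])
          record_screening(tr, pid, res$eligible, day)
          if (!res$eligible) {
            transition(tr, pid, "screen_fail", day)
          } else {
            transition(tr, pid, "start_run_in", day)
            dispense_run_in(tr, pid, day)
            push(rel + tr$config$runin_days, i)
          }
        } else if (st == "RUN_IN") {
          ae <- .with_rng(tr, stats::runif(1)) < cc$runin_ae_prob
          if (ae) {
            transition(tr, pid, "run_in_adverse_event", day)
          } else {
            randomize_treatment(tr, pid, day)
            dsp <- tryCatch(dispense(tr, pid, day),
                            trialops_stockout_error = function(e) e,
                            trialops_expiry_error = function(e) e)
            if (inherits(dsp, "error")) push(rel + 7L, i)
            else push(rel + dsp$days_covered, i)
          }
        } else if (st %in% dispensing_states) {
          if (day >= tr$p_trt_end[i]) {
            transition(tr, pid, "complete", day)
          } else {
            dsp <- tryCatch(dispense(tr, pid, day),
                            trialops_stockout_error = function(e) e,
                            trialops_expiry_error = function(e) e)
            if (inherits(dsp, "error")) {
              ## stock shortfall: retry after a week (an order will fire at
              ## the next monthly check if one is not already pending)
              push(rel + 7L, i)
            } else {
              push(rel + dsp$days_covered, i)
            }
          }
        }
        ## terminal/blocked participants simply drop off the schedule
      }
    }
  }

  end_day <- day
  res <- .sim_result(cc, tr, start, end_day, n_orders)
  res
}

.sim_result <- function(cc, tr, start, end_day, n_orders) {
  au <- trial_audit(tr)
  action <- au$action
  time <- as.numeric(au$date)
  payload <- au$payload
  month <- pmax(0, floor((time - start) / 31))

  n_from <- function(p) as.integer(sub(".*n=([0-9]+).*", "\\1", p))
  disp <- action == "dispense"
  dispensed_bottles <- if (any(disp)) sum(n_from(payload[disp])) else 0L
  disposed <- action == "dispose_expired"
  disposed_bottles <- if (any(disposed)) sum(n_from(payload[disposed])) else 0L

  tab <- function(flag) {
    if (!any(flag)) return(integer(0))
    table(month[flag])
  }
  months_idx <- 0:max(month, 0)
  cnt <- function(flag) {
    t <- tab(flag)
    out <- integer(length(months_idx))
    out[match(as.integer(names(t)), months_idx)] <- as.integer(t)
    out
  }
  monthly <- data.frame(
    month = months_idx,
    registered = cnt(action == "register"),
    screen_failed = cnt(action == "transition" &
                          grepl("SCREEN_FAILED", payload, fixed = TRUE)),
    randomized = cnt(action == "randomize_treatment"),
    withdrawn = cnt(action == "transition" &
                      grepl("\\|WITHDRAWN$", payload)),
    completed = cnt(action == "transition" &
                      grepl("\\|COMPLETED$", payload)),
    bottles_dispensed = vapply(months_idx, function(mm)
      sum(n_from(payload[disp & month == mm])), integer(1))
  )
  totals <- list(
    consented = sum(action == "register"),
    screen_failed = sum(action == "transition" &
                          grepl("SCREEN_FAILED", payload, fixed = TRUE)),
    randomized = sum(action == "randomize_treatment"),
    withdrawn = sum(action == "transition" & grepl("\\|WITHDRAWN$", payload)),
    completed = sum(action == "transition" & grepl("\\|COMPLETED$", payload)),
    bottles_generated = length(tr$b_code),
    bottles_loaded = sum(tr$k_n),
    bottles_dispensed = dispensed_bottles,
    bottles_disposed = disposed_bottles,
    bottles_in_stock = sum(tr$b_status == .ST_IN_STOCK),
    runin_units_dispensed = sum(action == "dispense_run_in"),
    n_orders = n_orders
  )
  structure(list(config = cc, trial = tr, totals = totals,
                 monthly = monthly, balance = balance_report(tr),
                 start_day = .as_date(start), end_day = .as_date(end_day)),
            class = "sim_result")
}

#' @export
print.sim_result <- function(x, ...) {
  t <- x$totals
  cat("Simulated trial (seed", x$config$seed, ")",
      format(x$start_day), "to", format(x$end_day), "\n")
  cat("  consented", t$consented, "| screen-failed", t$screen_failed,
      "| randomized", t$randomized, "| withdrawn", t$withdrawn,
      "| completed", t$completed, "\n")
  cat("  bottles: generated", t$bottles_generated, "| loaded",
      t$bottles_loaded, "| dispensed", t$bottles_dispensed, "| disposed",
      t$bottles_disposed, "| in stock", t$bottles_in_stock, "\n")
  cat("  run-in units dispensed", t$runin_units_dispensed, "| orders",
      t$n_orders, "\n")
  invisible(x)
}

#' Compare on-demand supply with the patients'-pack counterfactual
#'
#' Runs the on-demand simulation, then evaluates the patients'-pack policy
#' on the same realized cohort: every consented volunteer would have
#' received a full mean-treatment allotment up front, discounted by the
#' expected loss to follow-up.  If the simulation stopped mid-flight
#' (`run_months`), the bottles still needed to conclude are projected from
#' each active participant's remaining schedule and the screening/run-in
#' pipeline, discounted by the drop-out rate.
#'
#' @param config a [sim_config()].
#' @return a `strategy_comparison`: list with the `sim_result`,
#'   `theoretical_pp`, `dispensed`, `projected_to_end` and the
#'   [savings_report()].
#' @export
compare_strategies <- function(config) {
  res <- run_simulation(config)
  tr <- res$trial
  cc <- config
  n_cons <- res$totals$consented
  th <- patients_pack_requirement(n_cons, cc$treatment_months, cc$pp_loss)
  dispensed <- res$totals$bottles_dispensed

  end <- .day(res$end_day)
  active <- which(tr$p_state %in% c("TREATMENT_RANDOMIZED", "SUPPLY_STEP_1",
                                    "SUPPLY_STEP_2", "MAINTENANCE"))
  proj <- 0
  for (i in active) proj <- proj + .bottles_due(tr, i, end, Inf)
  per_completer <- .first_period_bottles(cc$treatment_months,
                                         tr$config$month_days)
  pipeline <- sum(tr$p_state == "RUN_IN") * (1 - cc$runin_ae_prob) *
    per_completer +
    sum(tr$p_state %in% c("REGISTERED", "DIET_RANDOMIZED")) *
    (1 - cc$screen_fail_prob) * (1 - cc$runin_ae_prob) * per_completer
  proj <- round((proj + pipeline) * (1 - cc$dropout_rate))

  sr <- savings_report(th, dispensed, proj, cc$unit_cost)
  structure(list(result = res, theoretical_pp = th, dispensed = dispensed,
                 projected_to_end = proj, savings = sr),
            class = "strategy_comparison")
}

#' @export
print.strategy_comparison <- function(x, ...) {
  cat("Strategy comparison (on-demand vs patients' packs)\n")
  print(x$savings)
  invisible(x)
}
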