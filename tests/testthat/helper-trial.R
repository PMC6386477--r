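# Shared fixtures, built in code.

TEST_START <- as.Date("2015-04-01")

# trial with an attached allocation, one loaded batch and run-in stock
make_stocked_trial <- function(seed = 1, n_bottles = 40,
                               expiry = TEST_START + 4 * 372,
                               key = "test-key") {
  tr <- trial_new(seed = seed)
  al <- generate_allocation_list(n_bottles, seed = seed + 100)
  attach_allocation(tr, al, key, date = TEST_START)
  load_batch(tr, "B001", "O001", TEST_START, expiry, al$code)
  add_runin_stock(tr, 50, TEST_START)
  tr
}

# register + diet-randomize + run-in; returns the id
add_runin_participant <- function(tr, id, sex = "female",
                                  birth = "1960-01-01",
                                  consent = TEST_START, family = NA) {
  register_participant(tr, id, sex, birth, consent, family)
  randomize_diet(tr, id)
  transition(tr, id, "start_run_in", consent + 20)
  dispense_run_in(tr, id, consent + 20)
  record_screening(tr, id, TRUE, consent + 20)
  id
}

# take a participant all the way to a blinded label
add_randomized_participant <- function(tr, id, sex = "female",
                                       birth = "1960-01-01",
                                       consent = TEST_START, family = NA) {
  add_runin_participant(tr, id, sex, birth, consent, family)
  randomize_treatment(tr, id, consent + 50)
  id
}

eligible_measures <- function() {
  baseline_measures(waist_cm = 92, glycemia_mg_dl = 104,
                    triglycerides_mg_dl = 165, hdl_mg_dl = 46,
                    systolic_mmHg = 136, diastolic_mmHg = 82,
                    creatinine_umol_l = 80)
}

# day-stepping enumeration of bottles scheduled within a horizon, used as
# the independent check on the forecasting A component
oracle_scheduled_bottles <- function(tr, today, horizon_months = 12) {
  d <- as.numeric(as.Date(today))
  to <- d + horizon_months * 31
  active <- c("TREATMENT_RANDOMIZED", "SUPPLY_STEP_1", "SUPPLY_STEP_2",
              "MAINTENANCE")
  step_after <- c(TREATMENT_RANDOMIZED = "SUPPLY_STEP_1",
                  SUPPLY_STEP_1 = "SUPPLY_STEP_2",
                  SUPPLY_STEP_2 = "MAINTENANCE",
                  MAINTENANCE = "MAINTENANCE")
  supply_of <- function(step, dose) required_supply(step, dose)
  total <- 0L
  p <- trial_participants(tr)
  for (i in seq_len(nrow(p))) {
    if (!p$state[i] %in% active) next
    due <- as.numeric(p$next_due[i])
    end <- as.numeric(p$treatment_end[i])
    dose <- p$dose_level[i]
    step <- step_after[[p$state[i]]]
    day <- due
    while (day <= to) {
      if (day == due) {
        if (day >= end) break
        rs <- supply_of(step, dose)
        if (day > d) total <- total + rs$bottles
        due <- due + rs$days
        step <- step_after[[step]]
      }
      day <- day + 1
    }
  }
  total
}

# chronological replay of all dispensations against the bottle table:
# checks the expiry guard and FEFO (no guard-eligible in-stock bottle of the
# same label expired earlier than the latest-expiring bottle dispensed)
check_dispensation_log <- function(tr) {
  reg <- allocation_register(tr)
  if (nrow(reg) == 0) return(TRUE)
  b <- trial_bottles(tr)
  batches <- trial_batches(tr)
  load_day <- as.numeric(batches$load_date)[match(b$batch_id,
                                                  batches$batch_id)]
  expiry <- as.numeric(b$expiry_date)
  avail <- !is.na(load_day)                  # ever loaded
  consumed <- rep(FALSE, nrow(b))
  reg <- reg[order(as.numeric(reg$date)), , drop = FALSE]
  ok <- TRUE
  for (r in seq_len(nrow(reg))) {
    t <- as.numeric(reg$date[r])
    days <- reg$days_covered[r]
    codes <- strsplit(reg$bottle_codes[r], ",")[[1]]
    j <- match(codes, b$code)
    lab <- unique(b$blinded_treatment[j])
    if (length(lab) != 1) return(FALSE)      # mixed labels in a dispensation
    exps <- expiry[j]
    if (any(exps < t + days)) return(FALSE)  # expired-drug guard violated
    in_stock <- which(avail & !consumed & b$blinded_treatment == lab &
                        load_day <= t)
    elig <- in_stock[expiry[in_stock] >= t + days]
    remaining <- setdiff(elig, j)
    if (length(remaining) && min(expiry[remaining]) < max(exps))
      return(FALSE)                          # FEFO violated
    consumed[j] <- TRUE
  }
  ok
}
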