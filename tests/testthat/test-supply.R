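test_that("short-dated deliveries are rejected at the 12-month rule", {
  tr <- trial_new(seed = 1)
  al <- generate_allocation_list(8, seed = 1)
  attach_allocation(tr, al, "k")
  # 13 months of shelf life: accepted
  load_batch(tr, "B13", "O1", TEST_START, TEST_START + 13 * 31,
             al$code[1:4])
  expect_identical(sum(tr$b_status == trialops:::.ST_IN_STOCK), 4L)
  # 11 months: rejected, citing the rule
  expect_error(load_batch(tr, "B11", "O2", TEST_START,
                          TEST_START + 11 * 31, al$code[5:8]),
               "12 months", class = "trialops_validation_error")
  # loading n bottles raises in-stock by exactly n
  load_batch(tr, "B2", "O3", TEST_START, TEST_START + 20 * 31, al$code[5:8])
  expect_identical(sum(tr$b_status == trialops:::.ST_IN_STOCK), 8L)
  expect_error(load_batch(tr, "B2", "O4", TEST_START, TEST_START + 700,
                          al$code[1:2]),
               class = "trialops_validation_error")  # duplicate batch
  expect_error(load_batch(tr, "B3", "O5", TEST_START, TEST_START + 700,
                          "NOPE"),
               class = "trialops_lookup_error")
})

test_that("the supply schedule matches the protocol", {
  s1 <- required_supply("SUPPLY_STEP_1")
  expect_identical(s1, list(bottles = 1L, days = 62L, tablets_per_day = 1L))
  s2 <- required_supply("SUPPLY_STEP_2")
  expect_identical(s2, list(bottles = 1L, days = 31L, tablets_per_day = 2L))
  mf <- required_supply("MAINTENANCE", "full")
  expect_identical(mf, list(bottles = 6L, days = 186L, tablets_per_day = 2L))
  mh <- required_supply("MAINTENANCE", "half")
  expect_identical(mh, list(bottles = 3L, days = 186L, tablets_per_day = 1L))
  ri <- required_supply("RUN_IN")
  expect_identical(ri$days, 30L)
  expect_error(required_supply("BOGUS"),
               class = "trialops_validation_error")
  # the full maintenance dose is 2 x 850 mg = 1700 mg/day
  expect_identical(mf$tablets_per_day * 850, 1700)
})

test_that("dispensing walks the steps and fills the register", {
  tr <- make_stocked_trial(seed = 2, n_bottles = 40)
  add_randomized_participant(tr, "P1")
  d1 <- dispense(tr, "P1", TEST_START + 50)
  expect_identical(d1$step, "SUPPLY_STEP_1")
  expect_identical(d1$next_due, TEST_START + 112)
  d2 <- dispense(tr, "P1", TEST_START + 112)
  expect_identical(d2$step, "SUPPLY_STEP_2")
  d3 <- dispense(tr, "P1", TEST_START + 143)
  expect_identical(d3$step, "MAINTENANCE")
  expect_length(d3$bottles, 6)

  reg <- allocation_register(tr)
  expect_identical(nrow(reg), 3L)
  expect_identical(sum(reg$n_bottles), 8L)
  # all bottles of one dispensation share the participant's label
  lab <- tr$p_label[1]
  b <- trial_bottles(tr)
  expect_true(all(b$blinded_treatment[match(d3$bottles, b$code)] == lab))
  # the register never names treatments
  expect_false(any(grepl("metformin|placebo",
                         utils::capture.output(print(reg)))))
})

test_that("FEFO picks the earliest-expiring eligible bottles", {
  tr <- trial_new(seed = 3)
  al <- generate_allocation_list(24, seed = 3)
  attach_allocation(tr, al, "k")
  add_runin_stock(tr, 5, TEST_START)
  # later-expiring batch loaded first
  load_batch(tr, "LATE", "O1", TEST_START, TEST_START + 900, al$code[1:12])
  load_batch(tr, "EARLY", "O2", TEST_START, TEST_START + 400,
             al$code[13:24])
  add_randomized_participant(tr, "P1")
  d <- dispense(tr, "P1", TEST_START + 50)
  b <- trial_bottles(tr)
  expect_identical(unique(b$batch_id[match(d$bottles, b$code)]), "EARLY")
  expect_true(check_dispensation_log(tr))
})

test_that("the expiry guard refuses stock that dies inside the window", {
  tr <- trial_new(seed = 4)
  al <- generate_allocation_list(40, seed = 4)
  attach_allocation(tr, al, "k")
  add_runin_stock(tr, 5, TEST_START)
  load_batch(tr, "B1", "O1", TEST_START - 400, TEST_START + 60, al$code)
  add_randomized_participant(tr, "P1")
  # step 1 needs 62 days of cover but everything expires in 60
  expect_error(dispense(tr, "P1", TEST_START + 50),
               class = "trialops_expiry_error")
  # stockout is the distinct failure when nothing is in stock at all
  dispose_expired(tr, TEST_START + 100)
  expect_error(dispense(tr, "P1", TEST_START + 101),
               class = "trialops_stockout_error")
})

test_that("expired stock is disposed and never dispensed afterwards", {
  tr <- trial_new(seed = 5)
  al <- generate_allocation_list(100, seed = 5)
  attach_allocation(tr, al, "k")
  load_batch(tr, "OLD", "O1", TEST_START - 400, TEST_START + 10,
             al$code[1:7])
  load_batch(tr, "NEW", "O2", TEST_START, TEST_START + 800, al$code[8:100])
  expect_identical(dispose_expired(tr, TEST_START), character(0))
  gone <- dispose_expired(tr, TEST_START + 11)
  expect_length(gone, 7)
  b <- trial_bottles(tr)
  expect_identical(sum(b$status == "disposed"), 7L)
  expect_identical(sum(b$status == "in_stock"), 93L)
  expect_true(inventory_conservation(tr))
  # disposed bottles can never come back
  add_runin_stock(tr, 5, TEST_START)
  add_randomized_participant(tr, "P1")
  d <- dispense(tr, "P1", TEST_START + 50)
  expect_false(any(d$bottles %in% gone))
})

test_that("a never-interrupted participant accumulates 62 + 62 + 372k tablets", {
  tr <- make_stocked_trial(seed = 6, n_bottles = 80,
                           expiry = TEST_START + 3000)
  add_randomized_participant(tr, "P1")
  d <- dispense(tr, "P1", TEST_START + 50)        # step 1: 62 tablets
  tablets <- length(d$bottles) * 62L
  d <- dispense(tr, "P1", d$next_due)             # step 2: 62 tablets
  tablets <- tablets + length(d$bottles) * 62L
  expect_identical(tablets, 124L)
  for (k in 1:2) {                                # maintenance cycles
    d <- dispense(tr, "P1", d$next_due)
    tablets <- tablets + length(d$bottles) * 62L
    expect_identical(tablets, 62L + 62L + 372L * k)
  }
})

test_that("run-in supplies come from their own open-label stock", {
  tr <- trial_new(seed = 7)
  al <- generate_allocation_list(8, seed = 7)
  attach_allocation(tr, al, "k")
  register_participant(tr, "P1", "male", "1960-01-01", TEST_START)
  randomize_diet(tr, "P1")
  transition(tr, "P1", "start_run_in", TEST_START + 20)
  expect_error(dispense_run_in(tr, "P1", TEST_START + 20),
               class = "trialops_stockout_error")
  add_runin_stock(tr, 2, TEST_START + 20)
  dispense_run_in(tr, "P1", TEST_START + 20)
  expect_identical(tr$runin_stock, 1L)
  expect_identical(tr$runin_dispensed, 1L)
  # blinded inventory untouched
  expect_identical(sum(tr$b_status == trialops:::.ST_GENERATED), 8L)
})
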