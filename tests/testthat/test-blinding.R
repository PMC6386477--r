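test_that("allocation blocks always hold two of each treatment", {
  al <- generate_allocation_list(4, seed = 1)
  expect_identical(nrow(al), 4L)
  expect_identical(unname(table(al$treatment)["metformin"]), 2L)
  expect_error(generate_allocation_list(6, seed = 1),
               class = "trialops_validation_error")
  expect_error(generate_allocation_list(0, seed = 1),
               class = "trialops_validation_error")

  al2 <- generate_allocation_list(400, seed = 5)
  comp <- tapply(al2$treatment, al2$block_id,
                 function(t) sum(t == "metformin"))
  expect_true(all(comp == 2))
  # cumulative 1:1 after any whole number of blocks
  cum_m <- cumsum(al2$treatment == "metformin")
  cum_p <- cumsum(al2$treatment == "placebo")
  at_blocks <- seq(4, 400, by = 4)
  expect_true(all(cum_m[at_blocks] == cum_p[at_blocks]))
  expect_false(any(duplicated(al2$code)))
})

test_that("a trial-scale list is reproducible and exactly half metformin", {
  al <- generate_allocation_list(200000, seed = 20)
  expect_identical(max(al$block_id), 50000L)
  expect_identical(as.vector(table(al$treatment)),
                   c(100000L, 100000L))
  al_again <- generate_allocation_list(200000, seed = 20)
  expect_identical(al, al_again)   # byte-for-byte from the seed
})

test_that("the manufacturer export carries codes and treatments only", {
  al <- generate_allocation_list(40, seed = 2)
  path <- withr::local_tempfile(fileext = ".csv")
  export_manufacturer_list(al, path)
  exp <- utils::read.csv(path, stringsAsFactors = FALSE)
  expect_identical(names(exp), c("code", "treatment"))
  expect_identical(nrow(exp), 40L)
  expect_setequal(unique(exp$treatment), c("metformin", "placebo"))
  # the schema has no participant field, so no id can ever appear
  expect_false(any(grepl("P[0-9]{5}", readLines(path))))
})

test_that("operational views expose blinded labels only", {
  tr <- make_stocked_trial(seed = 4)
  v <- operational_view(tr, tr$b_code[1])
  expect_true(v$blinded_treatment %in% c("X", "Y"))
  expect_identical(v$status, "in_stock")
  expect_false(v$blinded_treatment %in% c("metformin", "placebo"))
  # stable alias
  expect_identical(operational_view(tr, tr$b_code[1])$blinded_treatment,
                   v$blinded_treatment)
  expect_error(operational_view(tr, "NOPE"),
               class = "trialops_lookup_error")
})

test_that("only the PI can break the blind, and every decryption is audited", {
  tr <- make_stocked_trial(seed = 6)
  add_randomized_participant(tr, "P1")
  add_runin_participant(tr, "P2")

  expect_error(break_blind(tr, "P1", "dm", "data_manager", "urgent",
                           "test-key"),
               class = "trialops_auth_error")
  expect_error(break_blind(tr, "P2", "pi", "PI", "urgent", "test-key"),
               class = "trialops_state_error")
  expect_error(break_blind(tr, "P1", "pi", "PI", "", "test-key"),
               class = "trialops_validation_error")
  expect_error(break_blind(tr, "P1", "pi", "PI", "urgent", "wrong-key"),
               class = "trialops_auth_error")

  trt <- break_blind(tr, "P1", "pi", "PI", "hospital admission", "test-key")
  expect_true(trt %in% c("metformin", "placebo"))
  au <- trial_audit(tr)
  unblindings <- au[au$action == "break_blind", ]
  expect_identical(nrow(unblindings), 1L)
  expect_identical(unblindings$actor_role, "PI")
  expect_match(unblindings$payload, "hospital admission")
  # decryption count equals unblinding audit count
  expect_identical(tr$n_unseal, nrow(unblindings))

  # the alias map is consistent: same label, same treatment
  add_randomized_participant(tr, "P3")
  lab1 <- tr$p_label[match("P1", tr$p_id)]
  lab3 <- tr$p_label[match("P3", tr$p_id)]
  trt3 <- break_blind(tr, "P3", "pi", "PI", "major condition", "test-key")
  if (lab1 == lab3) expect_identical(trt3, trt) else
    expect_false(identical(trt3, trt))
})

test_that("sealed maps round-trip and reject tampering", {
  obj <- list(arm_map = c(X = "placebo", Y = "metformin"),
              bottle = c(B1 = "placebo"))
  s <- trialops:::.seal(obj, "k", "saltsalt")
  expect_identical(trialops:::.unseal(s, "k"), obj)
  s2 <- s
  s2$cipher[1] <- as.raw(bitwXor(as.integer(s2$cipher[1]), 255L))
  expect_error(trialops:::.unseal(s2, "k"), class = "trialops_auth_error")
})

test_that("operational outputs of a dispensing trial never name treatments", {
  tr <- make_stocked_trial(seed = 8)
  add_randomized_participant(tr, "P1")
  dispense(tr, "P1", TEST_START + 50)
  dispense(tr, "P1", TEST_START + 112)
  expect_identical(blind_scan(tr), 0L)
  # even after an unblinding, the scan (which redacts only that payload)
  # finds nothing elsewhere
  break_blind(tr, "P1", "pi", "PI", "emergency", "test-key")
  expect_identical(blind_scan(tr), 0L)
})
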