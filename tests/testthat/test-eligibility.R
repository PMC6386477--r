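test_that("metabolic criteria count matches the printed thresholds", {
  # three disorders, no treatments
  m <- baseline_measures(waist_cm = 90, glycemia_mg_dl = 105,
                         triglycerides_mg_dl = 160, hdl_mg_dl = 55,
                         systolic_mmHg = 120, diastolic_mmHg = 80)
  expect_identical(count_metabolic_criteria(m, "female"), 3L)

  # all strictly below the male cut-offs
  m0 <- baseline_measures(waist_cm = 99, glycemia_mg_dl = 99,
                          triglycerides_mg_dl = 149, hdl_mg_dl = 41,
                          systolic_mmHg = 129, diastolic_mmHg = 84)
  expect_identical(count_metabolic_criteria(m0, "male"), 0L)

  # boundary values are inclusive ("or more" / "or less")
  m5 <- baseline_measures(waist_cm = 85, glycemia_mg_dl = 100,
                          triglycerides_mg_dl = 150, hdl_mg_dl = 50,
                          systolic_mmHg = 130, diastolic_mmHg = 85)
  expect_identical(count_metabolic_criteria(m5, "female"), 5L)
})

test_that("treatment flags satisfy their criteria and BP is an OR rule", {
  base <- list(waist_cm = 70, glycemia_mg_dl = 90,
               triglycerides_mg_dl = 100, hdl_mg_dl = 60,
               systolic_mmHg = 110, diastolic_mmHg = 70)
  m <- do.call(baseline_measures, c(base, list(on_tg_treatment = TRUE,
                                               on_chol_treatment = TRUE,
                                               on_bp_treatment = TRUE)))
  expect_identical(count_metabolic_criteria(m, "female"), 3L)
  # diastolic alone can satisfy the blood-pressure criterion
  m2 <- do.call(baseline_measures,
                modifyList(base, list(diastolic_mmHg = 85)))
  expect_identical(count_metabolic_criteria(m2, "male"), 1L)
})

test_that("missing required fields raise a validation error naming them", {
  m <- baseline_measures(waist_cm = 90, glycemia_mg_dl = 105,
                         triglycerides_mg_dl = 160, hdl_mg_dl = 55,
                         systolic_mmHg = 120)
  expect_error(count_metabolic_criteria(m, "female"),
               "diastolic_mmHg", class = "trialops_validation_error")
  expect_error(baseline_measures(waist_cm = -1),
               class = "trialops_validation_error")
  expect_error(count_metabolic_criteria(eligible_measures(), "other"),
               class = "trialops_validation_error")
})

test_that("exclusion rules fire exactly as printed", {
  clear <- eligible_measures()
  expect_identical(check_exclusions(clear), character(0))

  cr <- baseline_measures(creatinine_umol_l = 125)
  expect_identical(check_exclusions(cr), "creatinine")
  expect_identical(check_exclusions(baseline_measures(creatinine_umol_l = 124)),
                   character(0))

  # the diabetes rule needs two repeated samples above 126
  g1 <- baseline_measures(glycemia_mg_dl = 130,
                          repeat_glycemia_mg_dl = 120)
  expect_identical(check_exclusions(g1), character(0))
  g2 <- baseline_measures(glycemia_mg_dl = 130,
                          repeat_glycemia_mg_dl = 131)
  expect_identical(check_exclusions(g2), "glycemia")

  all_bad <- baseline_measures(glycemia_mg_dl = 140,
                               repeat_glycemia_mg_dl = 140,
                               creatinine_umol_l = 200, proteinuria = TRUE,
                               on_metformin = TRUE, recent_cancer = TRUE,
                               on_excluded_drugs = TRUE,
                               excess_alcohol = TRUE)
  expect_setequal(check_exclusions(all_bad),
                  c("glycemia", "metformin", "cancer", "creatinine",
                    "proteinuria", "concomitant_drugs", "alcohol"))
})

test_that("adding a satisfied criterion never decreases the count", {
  set.seed(42)
  boosts <- list(
    waist = function(m) { m$waist_cm <- 120; m },
    glyc  = function(m) { m$glycemia_mg_dl <- 110; m },
    tg    = function(m) { m$on_tg_treatment <- TRUE; m },
    hdl   = function(m) { m$hdl_mg_dl <- 30; m },
    bp    = function(m) { m$on_bp_treatment <- TRUE; m }
  )
  for (rep in 1:50) {
    m <- baseline_measures(
      waist_cm = runif(1, 60, 130), glycemia_mg_dl = runif(1, 70, 130),
      triglycerides_mg_dl = runif(1, 80, 250),
      hdl_mg_dl = runif(1, 25, 80), systolic_mmHg = runif(1, 100, 170),
      diastolic_mmHg = runif(1, 60, 110))
    sex <- sample(c("male", "female"), 1)
    n0 <- count_metabolic_criteria(m, sex)
    for (boost in boosts) {
      m2 <- boost(unclass(m))
      class(m2) <- "baseline_measures"
      expect_gte(count_metabolic_criteria(m2, sex), n0)
    }
  }
})

test_that("screening combines criteria and exclusions", {
  res <- screen_eligibility(eligible_measures(), "female")
  expect_true(res$eligible)
  expect_gte(res$n_criteria, 3)
  bad <- eligible_measures()
  bad$proteinuria <- TRUE
  res2 <- screen_eligibility(bad, "female")
  expect_false(res2$eligible)
  expect_identical(res2$exclusions, "proteinuria")
})
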