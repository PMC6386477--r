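#' Baseline measurement record
#'
#' Bundles the anthropometric, blood and urine values taken at the baseline
#' visit, plus the boolean history flags used by the exclusion rules.
#' Concentrations and lengths must be non-negative.
#'
#' @param waist_cm waist circumference, cm.
#' @param glycemia_mg_dl fasting glycemia, mg/dL.
#' @param triglycerides_mg_dl triglycerides, mg/dL.
#' @param hdl_mg_dl HDL cholesterol, mg/dL.
#' @param systolic_mmHg,diastolic_mmHg blood pressure, mmHg.
#' @param on_tg_treatment,on_chol_treatment,on_bp_treatment receiving
#'   treatment for hypertriglyceridemia / hypercholesterolemia / high blood
#'   pressure.
#' @param repeat_glycemia_mg_dl optional second fasting sample, mg/dL
#'   (the diabetes exclusion requires two repeated samples above 126).
#' @param creatinine_umol_l serum creatinine, micromol/L.
#' @param proteinuria proteinuria present.
#' @param on_metformin concomitant metformin treatment.
#' @param recent_cancer cancer diagnosis in the last five years (skin
#'   carcinomas exempt; the flag is pre-computed on intake).
#' @param on_excluded_drugs potassium-sparing diuretics or proton pump
#'   inhibitors.
#' @param excess_alcohol excessive alcohol consumption (pre-computed flag).
#' @return a `baseline_measures` list.
#' @examples
#' m <- baseline_measures(waist_cm = 90, glycemia_mg_dl = 105,
#'                        triglycerides_mg_dl = 160, hdl_mg_dl = 55,
#'                        systolic_mmHg = 120, diastolic_mmHg = 80)
#' count_metabolic_criteria(m, "female")
#' @export
baseline_measures <- function(waist_cm = NA_real_,
                              glycemia_mg_dl = NA_real_,
                              triglycerides_mg_dl = NA_real_,
                              hdl_mg_dl = NA_real_,
                              systolic_mmHg = NA_real_,
                              diastolic_mmHg = NA_real_,
                              on_tg_treatment = FALSE,
                              on_chol_treatment = FALSE,
                              on_bp_treatment = FALSE,
                              repeat_glycemia_mg_dl = NA_real_,
                              creatinine_umol_l = NA_real_,
                              proteinuria = FALSE,
                              on_metformin = FALSE,
                              recent_cancer = FALSE,
                              on_excluded_drugs = FALSE,
                              excess_alcohol = FALSE) {
  m <- list(waist_cm = waist_cm, glycemia_mg_dl = glycemia_mg_dl,
            triglycerides_mg_dl = triglycerides_mg_dl,
            hdl_mg_dl = hdl_mg_dl, systolic_mmHg = systolic_mmHg,
            diastolic_mmHg = diastolic_mmHg,
            on_tg_treatment = isTRUE(on_tg_treatment),
            on_chol_treatment = isTRUE(on_chol_treatment),
            on_bp_treatment = isTRUE(on_bp_treatment),
            repeat_glycemia_mg_dl = repeat_glycemia_mg_dl,
            creatinine_umol_l = creatinine_umol_l,
            proteinuria = isTRUE(proteinuria),
            on_metformin = isTRUE(on_metformin),
            recent_cancer = isTRUE(recent_cancer),
            on_excluded_drugs = isTRUE(on_excluded_drugs),
            excess_alcohol = isTRUE(excess_alcohol))
  num <- c("waist_cm", "glycemia_mg_dl", "triglycerides_mg_dl", "hdl_mg_dl",
           "systolic_mmHg", "diastolic_mmHg", "repeat_glycemia_mg_dl",
           "creatinine_umol_l")
  for (f in num) {
    v <- m[[f]]
    if (!is.na(v) && v < 0)
      .err("validation_error", paste0(f, " must be non-negative"))
  }
  class(m) <- "baseline_measures"
  m
}

#' Count satisfied metabolic-syndrome criteria
#'
#' The five criteria, with sex-specific inclusive thresholds: abdominal
#' obesity (waist >= 85 cm women / >= 100 cm men), hyperglycemia
#' (>= 100 mg/dL), hypertriglyceridemia (>= 150 mg/dL or under treatment),
#' low HDL (<= 50 women / <= 40 men mg/dL or under cholesterol treatment),
#' high blood pressure (systolic >= 130 or diastolic >= 85 mmHg, or under
#' treatment).  Eligibility requires at least three of the five.
#'
#' @param m a [baseline_measures()] record.
#' @param sex `"male"` or `"female"`.
#' @return integer in 0..5.
#' @export
count_metabolic_criteria <- function(m, sex) {
  if (!inherits(m, "baseline_measures")) m <- do.call(baseline_measures, m)
  if (!sex %in% c("male", "female"))
    .err("validation_error", "sex must be 'male' or 'female'")
  req <- c("waist_cm", "glycemia_mg_dl", "triglycerides_mg_dl", "hdl_mg_dl",
           "systolic_mmHg", "diastolic_mmHg")
  miss <- req[vapply(req, function(f) is.na(m[[f]]), logical(1))]
  if (length(miss))
    .err("validation_error",
         paste0("missing required field(s): ", paste(miss, collapse = ", ")))
  waist_cut <- if (sex == "female") 85 else 100
  hdl_cut   <- if (sex == "female") 50 else 40
  crit <- c(
    waist  = m$waist_cm >= waist_cut,
    glyc   = m$glycemia_mg_dl >= 100,
    tg     = m$triglycerides_mg_dl >= 150 || m$on_tg_treatment,
    hdl    = m$hdl_mg_dl <= hdl_cut || m$on_chol_treatment,
    bp     = m$systolic_mmHg >= 130 || m$diastolic_mmHg >= 85 ||
             m$on_bp_treatment
  )
  sum(crit)
}

#' Check exclusion criteria
#'
#' Returns the names of every violated exclusion rule: fasting glycemia over
#' 126 mg/dL in two repeated samples, concomitant metformin, cancer in the
#' last five years, serum creatinine over 124 micromol/L, proteinuria,
#' excluded concomitant drugs (potassium-sparing diuretics or proton pump
#' inhibitors), excessive alcohol.  An empty vector means eligible on
#' exclusions.
#'
#' @param m a [baseline_measures()] record.
#' @return character vector of violated rule names (possibly empty).
#' @export
check_exclusions <- function(m) {
  if (!inherits(m, "baseline_measures")) m <- do.call(baseline_measures, m)
  out <- character(0)
  if (!is.na(m$glycemia_mg_dl) && m$glycemia_mg_dl > 126 &&
      !is.na(m$repeat_glycemia_mg_dl) && m$repeat_glycemia_mg_dl > 126)
    out <- c(out, "glycemia")
  if (m$on_metformin)      out <- c(out, "metformin")
  if (m$recent_cancer)     out <- c(out, "cancer")
  if (!is.na(m$creatinine_umol_l) && m$creatinine_umol_l > 124)
    out <- c(out, "creatinine")
  if (m$proteinuria)       out <- c(out, "proteinuria")
  if (m$on_excluded_drugs) out <- c(out, "concomitant_drugs")
  if (m$excess_alcohol)    out <- c(out, "alcohol")
  out
}

#' Screen a measurement record for eligibility
#'
#' @param m a [baseline_measures()] record.
#' @param sex `"male"` or `"female"`.
#' @return list with `eligible` (at least three criteria and no exclusions),
#'   `n_criteria`, and `exclusions`.
#' @export
screen_eligibility <- function(m, sex) {
  n <- count_metabolic_criteria(m, sex)
  ex <- check_exclusions(m)
  list(eligible = n >= 3 && length(ex) == 0, n_criteria = n, exclusions = ex)
}
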