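#' Register a participant
#'
#' Adds a consented volunteer to the roster in state `REGISTERED`.  The
#' first member registered under a `family_id` is the proband; relatives
#' registered later under the same `family_id` are familiars and will
#' inherit the proband's diet arm at [randomize_diet()].
#'
#' @param tr a [trial_new()] object.
#' @param id unique participant identifier.
#' @param sex `"male"` or `"female"`.
#' @param birth_date calendar date (Date or ISO-8601 string).
#' @param consent_date calendar date of informed consent.
#' @param family_id optional family token shared by co-enrolled relatives;
#'   `NA` for singletons.
#' @param actor,role audit attribution.
#' @return the participant id, invisibly.
#' @export
register_participant <- function(tr, id, sex, birth_date, consent_date,
                                 family_id = NA_character_,
                                 actor = "system", role = "data_manager") {
  stopifnot(inherits(tr, "trial"))
  if (!is.character(id) || length(id) != 1L || !nzchar(id))
    .err("validation_error", "participant id must be a non-empty string")
  if (id %in% tr$p_id)
    .err("validation_error", paste0("duplicate participant id: ", id))
  if (!sex %in% c("male", "female"))
    .err("validation_error", "sex must be 'male' or 'female'")
  bd <- .day(birth_date); cd <- .day(consent_date)
  if (is.na(bd) || is.na(cd) || bd >= cd)
    .err("validation_error", "birth_date must precede consent_date")
  proband <- is.na(family_id) || !family_id %in% tr$p_family

  n <- length(tr$p_id) + 1L
  tr$p_id[n]      <- id
  tr$p_sex[n]     <- sex
  tr$p_birth[n]   <- bd
  tr$p_family[n]  <- family_id
  tr$p_proband[n] <- proband
  tr$p_consent[n] <- cd
  tr$p_state[n]   <- "REGISTERED"
  tr$p_arm[n]     <- NA_character_
  tr$p_label[n]   <- NA_character_
  tr$p_dose[n]    <- "full"
  tr$p_regcomplete[n] <- FALSE
  tr$p_eligible[n]    <- NA
  tr$p_runin_start[n] <- NA_real_
  tr$p_runin_ae[n]    <- FALSE
  tr$p_rand_date[n]   <- NA_real_
  tr$p_trt_end[n]     <- NA_real_
  tr$p_next_due[n]    <- NA_real_
  tr$p_anniv[n]       <- cd + 365
  .audit(tr, consent_date, actor, role, "register", id,
         paste0("sex=", sex, ";proband=", proband))
  invisible(id)
}

#' Read participant intake records from CSV
#'
#' Expected header: `participant_id, sex, birth_date, family_id,
#' consent_date` with ISO-8601 dates; empty `family_id` means singleton.
#'
#' @param tr a [trial_new()] object.
#' @param path CSV file path.
#' @return number of participants registered, invisibly.
#' @export
import_participants <- function(tr, path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE,
                       colClasses = "character")
  need <- c("participant_id", "sex", "birth_date", "family_id",
            "consent_date")
  miss <- setdiff(need, names(d))
  if (length(miss))
    .err("validation_error",
         paste0("intake CSV missing column(s): ", paste(miss, collapse = ", ")))
  for (i in seq_len(nrow(d))) {
    fam <- d$family_id[i]
    if (is.na(fam) || !nzchar(fam)) fam <- NA_character_
    register_participant(tr, d$participant_id[i], d$sex[i],
                         d$birth_date[i], d$consent_date[i], fam)
  }
  invisible(nrow(d))
}

#' Record completion of the registration data set
#'
#' Treatment randomization is gated on complete registration data
#' (lifestyle questionnaire, 24-h diet diary, physical-activity diary,
#' concomitant medications) and on the baseline screening outcome; this
#' records both for a participant.
#'
#' @param tr a [trial_new()] object.
#' @param id participant identifier.
#' @param eligible logical screening outcome from [screen_eligibility()].
#' @param date record date.
#' @return invisibly, `eligible`.
#' @export
record_screening <- function(tr, id, eligible, date = Sys.Date()) {
  stopifnot(inherits(tr, "trial"))
  i <- .pidx(tr, id)
  tr$p_regcomplete[i] <- TRUE
  tr$p_eligible[i] <- isTRUE(eligible)
  .audit(tr, date, "system", "data_manager", "record_screening", id,
         paste0("eligible=", isTRUE(eligible)))
  invisible(eligible)
}
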