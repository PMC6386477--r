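## Marginal minimization.  `margins` is a list of length-2 named count
## vectors (one entry per arm) for the margins this participant falls in;
## the score of a candidate arm is the sum of post-assignment absolute
## imbalances across margins.  Exact score ties are broken deterministically
## on `primary` (post-assignment imbalance of a designated margin), and only
## then by a fair coin from the trial's seeded stream.  The deterministic
## tie-break on the overall margin is what keeps the overall arm difference
## within one for the diet randomization.
.minimize <- function(tr, margins, primary) {
  arms <- names(margins[[1]])
  sc <- vapply(seq_along(arms), function(a) {
    sum(vapply(margins, function(m) {
      m[a] <- m[a] + 1L
      abs(m[1] - m[2])
    }, numeric(1)))
  }, numeric(1))
  if (sc[1] != sc[2]) return(arms[which.min(sc)])
  pr <- vapply(seq_along(arms), function(a) {
    m <- primary; m[a] <- m[a] + 1L; abs(m[1] - m[2])
  }, numeric(1))
  if (pr[1] != pr[2]) return(arms[which.min(pr)])
  arms[if (.with_rng(tr, stats::runif(1)) < 0.5) 1L else 2L]
}

#' Diet randomization (active lifestyle intervention vs control)
#'
#' Assigns a registered participant to the blue (active lifestyle
#' intervention) or green (control) arm.  Members of the same family are
#' always placed in the same arm: a familiar whose family already has an
#' arm inherits it and does not touch the balancing counters.  Probands are
#' assigned by deterministic marginal minimization over the overall arm
#' totals and the sex margin, ties broken by a seeded coin.  Assignments
#' are immutable.
#'
#' @param tr a [trial_new()] object.
#' @param id participant identifier (state must be `REGISTERED`).
#' @param date randomization date (defaults to the consent date).
#' @return the assigned arm, `"blue"` or `"green"`.
#' @export
randomize_diet <- function(tr, id, date = NULL) {
  stopifnot(inherits(tr, "trial"))
  i <- .pidx(tr, id)
  if (!is.na(tr$p_arm[i]))
    .err("state_error", paste0(id, " is already diet-randomized"))
  if (tr$p_state[i] != "REGISTERED")
    .err("state_error", paste0("diet randomization requires state REGISTERED (",
                               id, " is ", tr$p_state[i], ")"))
  if (is.null(date)) date <- tr$p_consent[i]
  fam <- tr$p_family[i]
  inherited <- FALSE
  if (!is.na(fam)) {
    fam_arms <- tr$p_arm[!is.na(tr$p_family) & tr$p_family == fam &
                         !is.na(tr$p_arm)]
    if (length(fam_arms)) {
      arm <- fam_arms[1]
      inherited <- TRUE
    }
  }
  if (!inherited) {
    sex <- tr$p_sex[i]
    led <- tr$led_diet
    arm <- .minimize(tr,
                     margins = list(overall = rowSums(led), sex = led[, sex]),
                     primary = rowSums(led))
    if (tr$p_proband[i]) tr$led_diet[arm, sex] <- led[arm, sex] + 1L
  }
  tr$p_arm[i] <- arm
  transition(tr, id, "diet_randomize", date)
  .audit(tr, date, "system", "data_manager", "randomize_diet", id,
         paste0("arm=", arm, ";inherited=", inherited,
                ";counters=", paste(as.vector(tr$led_diet), collapse = ",")))
  arm
}

#' Treatment randomization (blinded label X vs Y)
#'
#' Unlocked only when the participant has completed the 30-day run-in with
#' no adverse events, the registration data set is complete and eligibility
#' is satisfied.  Assigns the blinded label by minimization over the sex
#' and age-group (up to 67 / over 67 at randomization) margins; the label
#' is an alias — the drug name is only reachable via [break_blind()].
#'
#' @param tr a [trial_new()] object.
#' @param id participant identifier (state must be `RUN_IN`).
#' @param date randomization date.
#' @return the assigned blinded label, `"X"` or `"Y"`.
#' @export
randomize_treatment <- function(tr, id, date) {
  stopifnot(inherits(tr, "trial"))
  i <- .pidx(tr, id)
  d <- .day(date)
  if (tr$p_state[i] != "RUN_IN")
    .err("state_error",
         paste0("treatment randomization requires state RUN_IN (", id,
                " is ", tr$p_state[i], ")"))
  if (tr$p_runin_ae[i])
    .err("gating_error", "gating error: adverse event during run-in")
  if (is.na(tr$p_runin_start[i]) ||
      d < tr$p_runin_start[i] + tr$config$runin_days)
    .err("gating_error", "gating error: 30-day run-in not complete")
  if (!tr$p_regcomplete[i])
    .err("gating_error", "gating error: registration data incomplete")
  if (!isTRUE(tr$p_eligible[i]))
    .err("gating_error", "gating error: eligibility not satisfied")

  sex <- tr$p_sex[i]
  age <- floor((d - tr$p_birth[i]) / 365.25)
  grp <- if (age <= tr$config$age_cut) "le67" else "gt67"
  overall <- rowSums(tr$led_trt_sex)
  label <- .minimize(tr,
                     margins = list(sex = tr$led_trt_sex[, sex],
                                    age = tr$led_trt_age[, grp]),
                     primary = overall)
  tr$led_trt_sex[label, sex] <- tr$led_trt_sex[label, sex] + 1L
  tr$led_trt_age[label, grp] <- tr$led_trt_age[label, grp] + 1L
  tr$p_label[i] <- label
  tr$p_rand_date[i] <- d
  tr$rand_times[length(tr$rand_times) + 1L] <- d
  tr$p_trt_end[i] <- d + tr$config$treatment_months * tr$config$month_days
  tr$p_next_due[i] <- d
  transition(tr, id, "treatment_randomize", date)
  .audit(tr, date, "system", "data_manager", "randomize_treatment", id,
         paste0("label=", label, ";age_group=", grp,
                ";counters=", paste(c(as.vector(tr$led_trt_sex),
                                      as.vector(tr$led_trt_age)),
                                    collapse = ",")))
  label
}

#' Randomization balance report
#'
#' The proband/familiar by arm by sex table the data manager can consult at
#' any time, with row and column totals, per-margin absolute imbalances and
#' a family-consistency flag.
#'
#' @param x a `trial`, or a data frame with columns `is_proband` (or
#'   `role`), `diet_arm`, `sex` and optionally `family_id`.
#' @param ... unused.
#' @return a `balance_report`: list with the 2x4 `table` (rows proband /
#'   familiar; columns blue.male, blue.female, green.male, green.female),
#'   `row_totals`, `col_totals`, `grand_total`, `arm_totals`,
#'   `proband_arm_imbalance` and `family_consistent`.
#' @export
balance_report <- function(x, ...) UseMethod("balance_report")

#' @export
balance_report.trial <- function(x, ...) {
  keep <- !is.na(x$p_arm)
  d <- data.frame(
    role = ifelse(x$p_proband[keep], "proband", "familiar"),
    diet_arm = x$p_arm[keep], sex = x$p_sex[keep],
    family_id = x$p_family[keep], stringsAsFactors = FALSE
  )
  balance_report.data.frame(d)
}

#' @export
balance_report.data.frame <- function(x, ...) {
  if (!"role" %in% names(x) && "is_proband" %in% names(x))
    x$role <- ifelse(x$is_proband, "proband", "familiar")
  tab <- matrix(0L, 2, 4,
                dimnames = list(c("proband", "familiar"),
                                c("blue.male", "blue.female",
                                  "green.male", "green.female")))
  if (nrow(x)) {
    cell <- paste(x$diet_arm, x$sex, sep = ".")
    cnt <- table(factor(x$role, levels = rownames(tab)),
                 factor(cell, levels = colnames(tab)))
    tab[] <- as.integer(cnt)
  }
  arm_tot <- c(blue = sum(tab[, 1:2]), green = sum(tab[, 3:4]))
  prob_arm <- c(blue = sum(tab["proband", 1:2]),
                green = sum(tab["proband", 3:4]))
  fam_ok <- NA
  if ("family_id" %in% names(x)) {
    fam <- x$family_id[!is.na(x$family_id)]
    if (length(fam)) {
      arms_per_fam <- tapply(x$diet_arm[!is.na(x$family_id)], fam,
                             function(a) length(unique(a)))
      fam_ok <- all(arms_per_fam == 1L)
    } else fam_ok <- TRUE
  }
  out <- list(table = tab,
              row_totals = stats::setNames(as.integer(rowSums(tab)),
                                           rownames(tab)),
              col_totals = stats::setNames(as.integer(colSums(tab)),
                                           colnames(tab)),
              grand_total = sum(tab),
              arm_totals = arm_tot,
              proband_arm_totals = prob_arm,
              proband_arm_imbalance = abs(prob_arm[1] - prob_arm[2]),
              family_consistent = fam_ok)
  class(out) <- "balance_report"
  out
}

#' @export
print.balance_report <- function(x, ...) {
  cat("Diet randomization balance\n")
  m <- cbind(x$table, Total = x$row_totals)
  m <- rbind(m, Total = c(x$col_totals, x$grand_total))
  print(m)
  cat("proband arm totals: blue", x$proband_arm_totals[["blue"]],
      "/ green", x$proband_arm_totals[["green"]],
      "(imbalance", x$proband_arm_imbalance, ")\n")
  if (!is.na(x$family_consistent))
    cat("family consistency:", if (x$family_consistent) "OK" else "VIOLATED",
        "\n")
  invisible(x)
}

#' Export a balance report to CSV
#'
#' @param x a `balance_report`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
export_balance_report <- function(x, path) {
  stopifnot(inherits(x, "balance_report"))
  m <- cbind(x$table, Total = x$row_totals)
  m <- rbind(m, Total = c(x$col_totals, x$grand_total))
  utils::write.csv(as.data.frame(m), path, row.names = TRUE)
  invisible(path)
}
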