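#' Load the recruited-cohort balance counts
#'
#' The published diet-randomization balance of the recruited cohort: the
#' proband/familiar by blue/green by male/female cell counts (probands
#' 327/479/349/456, familiars 13/68/5/58; 1755 volunteers in total),
#' shipped with the package as a plain-CSV fixture.
#'
#' @return a `balance_counts` data frame with columns `role`, `arm`, `sex`,
#'   `count`.
#' @examples
#' cnt <- load_balance_fixture()
#' sum(cnt$count)  # 1755
#' @export
load_balance_fixture <- function() {
  path <- system.file("extdata", "diet_balance_counts.csv",
                      package = "trialops")
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  class(d) <- c("balance_counts", "data.frame")
  d
}

#' @export
balance_report.balance_counts <- function(x, ...) {
  d <- x[rep(seq_len(nrow(x)), x$count), c("role", "arm", "sex")]
  names(d)[2] <- "diet_arm"
  balance_report.data.frame(d)
}

#' Expand balance counts into synthetic participant records
#'
#' Builds one synthetic participant row per counted individual: probands
#' each found a family; familiars are attached to a family whose proband
#' has the same diet arm, so the family-consistency rule holds by
#' construction.  Demographic dates are synthetic placeholders.
#'
#' @param counts a `balance_counts` data frame (default the shipped
#'   fixture).
#' @return data frame with columns `participant_id`, `sex`, `birth_date`,
#'   `family_id`, `is_proband`, `consent_date`, `diet_arm`, `role`.
#' @export
balance_fixture_participants <- function(counts = load_balance_fixture()) {
  rows <- counts[rep(seq_len(nrow(counts)), counts$count),
                 c("role", "arm", "sex")]
  rownames(rows) <- NULL
  n <- nrow(rows)
  pid <- sprintf("P%05d", seq_len(n))
  fam <- character(n)
  is_prob <- rows$role == "proband"
  fam[is_prob] <- sprintf("F%05d", seq_len(sum(is_prob)))
  ## attach each familiar to a proband family with the matching arm
  for (arm in unique(rows$arm)) {
    fi <- which(!is_prob & rows$arm == arm)
    hosts <- fam[is_prob & rows$arm == arm]
    if (length(fi))
      fam[fi] <- hosts[((seq_along(fi) - 1L) %% length(hosts)) + 1L]
  }
  data.frame(participant_id = pid, sex = rows$sex,
             birth_date = as.Date("1960-01-01"),
             family_id = fam, is_proband = is_prob,
             consent_date = as.Date("2015-04-01"),
             diet_arm = rows$arm, role = rows$role,
             stringsAsFactors = FALSE)
}
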