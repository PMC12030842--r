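#' Baseline cancer incidence for one site and sex
#'
#' Holds the baseline (unexposed) incidence rate lambda_c(a) per person-year
#' on the same integer age grid as the life table it is used with.
#'
#' @param site Cancer-site label.
#' @param sex `"male"` or `"female"`.
#' @param ages Integer age grid (must match the companion life table).
#' @param rate Baseline incidence per person-year at each age; all `>= 0`.
#' @return An object of class `baseline_incidence`.
#' @export
baseline_incidence <- function(site, sex, ages, rate) {
  sex <- match.arg(sex, c("male", "female"))
  if (length(ages) != length(rate))
    .input_error("baseline_incidence(): ages and rate lengths differ")
  if (any(rate < 0)) .input_error("baseline_incidence(): negative incidence rate")
  structure(list(site = site, sex = sex, ages = as.integer(ages),
                 rate_by_age = as.numeric(rate)),
            class = "baseline_incidence")
}

.baseline_key <- function(site, sex) paste(site, sex, sep = "|")

#' Look up a baseline incidence object in a bundle
#'
#' @param baselines Named list of `baseline_incidence` objects as produced by
#'   [illustrative_baselines()].
#' @param site,sex Site label and sex.
#' @return A `baseline_incidence`.
#' @export
get_baseline <- function(baselines, site, sex) {
  b <- baselines[[.baseline_key(site, sex)]]
  if (is.null(b))
    .config_error(sprintf("no baseline incidence for site '%s', sex '%s'", site, sex))
  b
}

# Illustrative site catalogue shared by the bundled models. rate60_* are
# baseline incidence per person-year at age 60; incidence rises as
# (age/60)^power above age 20 and is flat below. beta_err is ERR per Gy,
# beta_ear is excess cases per 10^4 person-year-Gy. Values are
# order-of-magnitude plausible, NOT the official model coefficients.
.site_catalogue <- function() {
  data.frame(
    site   = c("bladder", "bone", "breast", "colon", "esophagus", "kidney",
               "liver", "lung", "other_solid", "ovary", "prostate", "skin",
               "stomach", "thyroid", "uterus", "leukemia"),
    sexes  = c("both", "both", "female", "both", "both", "both",
               "both", "both", "both", "female", "male", "both",
               "both", "both", "female", "both"),
    class  = c(rep("solid", 15), "leukemia"),
    beta_err = c(0.50, 0.10, 0.50, 0.60, 0.40, 0.30,
                 0.35, 0.40, 0.30, 0.40, 0.12, 0.20,
                 0.25, 0.50, 0.06, 1.10),
    beta_ear = c(1.0, 0.2, 6.0, 2.4, 0.6, 0.6,
                 2.0, 3.4, 3.0, 0.7, 0.8, 1.5,
                 3.3, 0.4, 1.0, 0.8),
    rate60_male   = c(5e-4, 2e-5, NA,     9e-4, 2.0e-4, 4e-4,
                      3e-4, 1.2e-3, 1.0e-3, NA,  2.5e-3, 5e-4,
                      4e-4, 1e-4, NA,     3e-4),
    rate60_female = c(1.5e-4, 2e-5, 1.9e-3, 7e-4, 7e-5, 2e-4,
                      1.5e-4, 8e-4, 8e-4,  3e-4, NA,    4e-4,
                      2e-4, 3e-4, 6e-4,   2e-4),
    power = c(rep(4, 15), 2),
    stringsAsFactors = FALSE
  )
}

#' Illustrative baseline incidence bundle
#'
#' Smooth parametric incidence curves lambda_c(a) = r60 * (max(a, 20)/60)^p
#' for every site and sex covered by the bundled model families. The rates
#' are plausible in magnitude for an adult Western population but are not
#' registry values; supply registry-derived `baseline_incidence` objects for
#' real analyses.
#'
#' @param ages Integer age grid (default `0:100`).
#' @return Named list of `baseline_incidence` objects keyed `"site|sex"`.
#' @export
illustrative_baselines <- function(ages = 0:100) {
  cat <- .site_catalogue()
  out <- list()
  for (i in seq_len(nrow(cat))) {
    for (sex in c("male", "female")) {
      r60 <- cat[[paste0("rate60_", sex)]][i]
      if (is.na(r60)) next
      rate <- r60 * (pmax(ages, 20) / 60)^cat$power[i]
      out[[.baseline_key(cat$site[i], sex)]] <-
        baseline_incidence(cat$site[i], sex, ages, rate)
    }
  }
  out
}
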