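#' Specification of a synthetic ICU cohort
#'
#' Defaults reproduce the statistical structure of the study population the
#' package emulates: 71 adult ICU patients, 58 male / 13 female, age median
#' 66 (IQR 56-71) years, a right-skewed per-patient cumulative effective
#' dose with IQR 17.34-84.64 mSv, an exam mix of 87% radiographs / 9% CT /
#' 4% fluoroscopy-interventional, and about 40 irradiation events per
#' patient (2847 events over 71 patients).
#'
#' @param n_patients Number of patients (default 71).
#' @param male_fraction Proportion male (default 58/71).
#' @param age_quartiles `c(q1, median, q3)` of age in years, strictly
#'   increasing (default `c(56, 66, 71)`).
#' @param dose_quartiles `c(q1, q3)` in mSv of the lognormal cumulative-dose
#'   model (default `c(17.34, 84.64)`).
#' @param event_mix Named proportions over
#'   `c(radiograph, ct, fluoro_ir)`, summing to 1 (default
#'   `c(0.87, 0.09, 0.04)`).
#' @param mean_events_per_patient Mean irradiation events per patient
#'   (default 2847/71).
#' @param los_quartiles `c(q1, median-ignored, q3)` is not needed:
#'   hospitalization length (days) uses a lognormal fit to `c(15, 70)`
#'   (reporting only; it does not drive dose).
#' @param seed Integer RNG seed (default 1).
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_patients = 71, male_fraction = 58 / 71,
                        age_quartiles = c(56, 66, 71),
                        dose_quartiles = c(17.34, 84.64),
                        event_mix = c(radiograph = 0.87, ct = 0.09,
                                      fluoro_ir = 0.04),
                        mean_events_per_patient = 2847 / 71,
                        los_quartiles = c(15, 70),
                        seed = 1L) {
  if (n_patients < 1) .input_error("cohort_spec(): need at least 1 patient")
  if (male_fraction < 0 || male_fraction > 1)
    .input_error("cohort_spec(): male_fraction outside [0, 1]")
  if (any(diff(age_quartiles) <= 0) || length(age_quartiles) != 3L)
    .input_error("cohort_spec(): age_quartiles must be 3 strictly increasing values")
  if (length(dose_quartiles) != 2L || dose_quartiles[1] <= 0 ||
      diff(dose_quartiles) <= 0)
    .input_error("cohort_spec(): dose_quartiles must be 0 < q1 < q3")
  if (!all(sort(names(event_mix)) == c("ct", "fluoro_ir", "radiograph")) ||
      any(event_mix < 0) || abs(sum(event_mix) - 1) > 1e-9)
    .input_error("cohort_spec(): event_mix must cover radiograph/ct/fluoro_ir and sum to 1")
  if (mean_events_per_patient <= 0)
    .input_error("cohort_spec(): mean_events_per_patient must be > 0")
  structure(list(n_patients = as.integer(n_patients),
                 male_fraction = male_fraction,
                 age_quartiles = age_quartiles,
                 dose_quartiles = dose_quartiles,
                 event_mix = event_mix,
                 mean_events_per_patient = mean_events_per_patient,
                 los_quartiles = los_quartiles,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Lognormal parameters from two quartiles
#'
#' The two-parameter lognormal whose theoretical 25th and 75th percentiles
#' equal `q1` and `q3`: meanlog = (log q1 + log q3)/2, sdlog =
#' (log q3 - log q1) / (2 z), z the standard normal upper-quartile deviate.
#' The implied median is sqrt(q1 * q3).
#'
#' @param q1,q3 Lower and upper quartile, `0 < q1 < q3`.
#' @return List: `meanlog`, `sdlog`, `median`.
#' @export
lognormal_from_quartiles <- function(q1, q3) {
  if (q1 <= 0 || q3 <= q1)
    .input_error("lognormal_from_quartiles(): need 0 < q1 < q3")
  z <- stats::qnorm(0.75)
  meanlog <- (log(q1) + log(q3)) / 2
  sdlog <- (log(q3) - log(q1)) / (2 * z)
  list(meanlog = meanlog, sdlog = sdlog, median = exp(meanlog))
}

# two-piece normal matched to three quartiles: half the mass on each side of
# the median, side-specific spreads from the printed asymmetric quartiles
.rtwopiece <- function(n, q) {
  z <- stats::qnorm(0.75)
  sdl <- (q[2] - q[1]) / z
  sdr <- (q[3] - q[2]) / z
  left <- stats::runif(n) < 0.5
  mag <- abs(stats::rnorm(n))
  ifelse(left, q[2] - mag * sdl, q[2] + mag * sdr)
}

# event-dose weights: relative typical effective dose per modality, used to
# split a patient's target cumulative dose across their events
.modality_weights <- c(radiograph = 1, fluoro_ir = 100, ct = 300)

#' Generate a synthetic ICU cohort and exposure-event log
#'
#' Deterministic given the spec's seed. Sexes are Bernoulli draws, ages come
#' from an asymmetric two-piece normal matched to the three age quartiles
#' (truncated to 18-99), per-patient target cumulative doses from the
#' lognormal fit to the dose quartiles, and event counts from a Poisson
#' (floor 1) with modalities drawn from the event mix. Event dose metrics
#' are back-solved so that each patient's event doses sum exactly to the
#' target: fluoroscopy events invert DAP = dose/k, CT events invert
#' DLP = dose/ct_k, radiograph events carry a precomputed effective-dose
#' override (their engine path is a fixed per-region median that cannot be
#' inverted per event). Feeding the event log through the dose engine
#' therefore reproduces the target cumulative doses to rounding error.
#'
#' @param spec A `cohort_spec`.
#' @param cf Conversion factors used for the back-solving (default
#'   [default_conversion_factors()]); use the same factors downstream.
#' @return List of class `synthetic_cohort`: `patients` (data.frame with
#'   `patient_id`, `sex`, `age_at_admission`, `hospitalization_days`,
#'   `n_events`, `cumulative_effective_dose_msv`), `events` (event-log
#'   data.frame), `spec`.
#' @export
generate_cohort <- function(spec, cf = default_conversion_factors()) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  n <- spec$n_patients
  sex <- ifelse(stats::runif(n) < spec$male_fraction, "male", "female")
  age <- .rtwopiece(n, spec$age_quartiles)
  for (it in 1:100) {                      # truncate to [18, 99] by redraw
    bad <- age < 18 | age > 99
    if (!any(bad)) break
    age[bad] <- .rtwopiece(sum(bad), spec$age_quartiles)
  }
  age <- pmin(pmax(age, 18), 99)
  age <- round(age, 1)
  lp <- lognormal_from_quartiles(spec$dose_quartiles[1], spec$dose_quartiles[2])
  target <- stats::rlnorm(n, lp$meanlog, lp$sdlog)
  los_p <- lognormal_from_quartiles(spec$los_quartiles[1], spec$los_quartiles[2])
  los <- round(stats::rlnorm(n, los_p$meanlog, los_p$sdlog))
  n_ev <- pmax(1L, stats::rpois(n, spec$mean_events_per_patient))
  pid <- sprintf("P%04d", seq_len(n))
  ev_pid <- rep(pid, n_ev)
  ev_idx <- rep(seq_len(n), n_ev)
  total_ev <- sum(n_ev)
  modality <- sample(names(spec$event_mix), total_ev, replace = TRUE,
                     prob = spec$event_mix)
  region <- character(total_ev)
  is_rad <- modality == "radiograph"
  is_ct <- modality == "ct"
  is_fl <- modality == "fluoro_ir"
  region[is_rad] <- sample(c("chest", "abdomen", "limb", "spine"),
                           sum(is_rad), replace = TRUE,
                           prob = c(0.80, 0.08, 0.06, 0.06))
  region[is_ct] <- sample(c("chest", "abdomen"), sum(is_ct), replace = TRUE,
                          prob = c(0.45, 0.55))
  region[is_fl] <- sample(c("abdomen", "chest"), sum(is_fl), replace = TRUE,
                          prob = c(0.6, 0.4))
  w <- .modality_weights[modality]
  wsum <- as.numeric(rowsum(w, factor(ev_idx, levels = seq_len(n))))
  ev_dose <- target[ev_idx] * w / wsum[ev_idx]
  dap <- dlp <- override <- rep(NA_real_, total_ev)
  override[is_rad] <- ev_dose[is_rad]
  dap[is_fl] <- ev_dose[is_fl] / cf$fluoro_k[region[is_fl]]
  dlp[is_ct] <- ev_dose[is_ct] / cf$ct_k[region[is_ct]]
  events <- data.frame(
    patient_id = ev_pid, sex = sex[ev_idx], age = age[ev_idx],
    event_type = modality, body_region = region,
    dap_mgycm2 = dap, dlp_mgycm = dlp,
    effective_dose_msv = override, stringsAsFactors = FALSE)
  patients <- data.frame(
    patient_id = pid, sex = sex, age_at_admission = age,
    hospitalization_days = los, n_events = n_ev,
    cumulative_effective_dose_msv =
      as.numeric(rowsum(ev_dose, factor(ev_idx, levels = seq_len(n)))),
    stringsAsFactors = FALSE)
  structure(list(patients = patients, events = events, spec = spec),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("<synthetic_cohort> %d patients, %d events (seed %d)\n",
              nrow(x$patients), nrow(x$events), x$spec$seed))
  invisible(x)
}

#' Cohort characteristics table
#'
#' Patient counts by sex and median (IQR) of age and hospitalization length,
#' overall and by sex — the layout of a patient-characteristics table.
#'
#' @param patients Patient data.frame (needs `sex`, `age_at_admission`;
#'   `hospitalization_days` optional).
#' @return List of class `cohort_report`.
#' @export
cohort_report <- function(patients) {
  if (nrow(patients) == 0L) .input_error("cohort_report(): empty cohort")
  by_sex <- function(x, s) x[patients$sex == s]
  rep_var <- function(x) list(
    overall = as.list(median_iqr(x)),
    male = if (any(patients$sex == "male")) as.list(median_iqr(by_sex(x, "male"))) else NULL,
    female = if (any(patients$sex == "female")) as.list(median_iqr(by_sex(x, "female"))) else NULL)
  out <- list(
    n = nrow(patients),
    n_male = sum(patients$sex == "male"),
    n_female = sum(patients$sex == "female"),
    age_years = rep_var(patients$age_at_admission))
  if ("hospitalization_days" %in% names(patients))
    out$hospitalization_days <- rep_var(patients$hospitalization_days)
  structure(out, class = "cohort_report")
}

#' @export
print.cohort_report <- function(x, ...) {
  cat(sprintf("Cohort: %d patients (%d male, %d female)\n",
              x$n, x$n_male, x$n_female))
  cat(sprintf("  age: median %.1f (IQR %.1f-%.1f) years\n",
              x$age_years$overall$median, x$age_years$overall$q1,
              x$age_years$overall$q3))
  if (!is.null(x$hospitalization_days))
    cat(sprintf("  hospitalization: median %.0f (IQR %.0f-%.0f) days\n",
                x$hospitalization_days$overall$median,
                x$hospitalization_days$overall$q1,
                x$hospitalization_days$overall$q3))
  invisible(x)
}
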