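#' Excess relative risk of the default projection form
#'
#' ERR(D, e, a) = beta * D * exp(gamma * e*) * (a/60)^eta with
#' e* = (min(e, 30) - 30)/10. Linear in dose (linear no-threshold), with the
#' usual exponential age-at-exposure modifier (saturating at age 30) and a
#' power-law attained-age modifier centred at age 60.
#'
#' @param coeffs A `pathway_coefficients` object.
#' @param dose Dose in Gy, `>= 0`.
#' @param age_at_exposure Age at exposure e (years).
#' @param attained_age Attained age a (years), `>= e`.
#' @return Unitless excess relative risk (vectorised over `attained_age`).
#' @export
excess_relative_risk <- function(coeffs, dose, age_at_exposure, attained_age) {
  if (dose < 0) .input_error("excess_relative_risk(): negative dose")
  if (any(attained_age < age_at_exposure))
    .input_error("excess_relative_risk(): attained age below exposure age")
  estar <- (min(age_at_exposure, 30) - 30) / 10
  coeffs$beta * dose * exp(coeffs$gamma * estar) * (attained_age / 60)^coeffs$eta
}

# dose-response factor replacing beta*dose: solid sites are linear with the
# DDREF divisor; leukemia is linear-quadratic dose*(beta + theta*dose) with
# no DDREF (the curvature itself plays that role at low dose rate)
.dose_response <- function(beta, dose, ddref, class, theta) {
  if (class == "leukemia") dose * (beta + theta * dose) else beta * dose / ddref
}

#' Excess absolute cancer rate M(D, e, a)
#'
#' The excess incidence per person-year at attained age `a` from a dose `D`
#' received at age `e`, for one projection pathway. The ERR pathway returns
#' ERR * lambda_c(a); the EAR pathway returns the same functional form with
#' beta in absolute units (excess cases per 10,000 person-year-Gy, converted
#' to per person-year). Within the site-class latency window the excess is 0
#' by contract. Leukemia uses the linear-quadratic dose response
#' dose*(beta + theta*dose); solid sites divide the linear term by the
#' model's DDREF.
#'
#' @param model A `risk_model_spec`.
#' @param baseline A `baseline_incidence` (supplies site, sex and
#'   lambda_c(a)).
#' @param pathway `"ERR"` or `"EAR"`.
#' @param dose Dose in Gy.
#' @param e Age at exposure (years).
#' @param a Attained age(s), years; vectorised.
#' @return Excess incidence per person-year, same length as `a`.
#' @export
excess_absolute_rate <- function(model, baseline, pathway = c("ERR", "EAR"),
                                 dose, e, a) {
  pathway <- match.arg(pathway)
  if (dose < 0) .input_error("excess_absolute_rate(): negative dose")
  cls <- .site_class(model, baseline$site)
  cf <- model_coefficients(model, baseline$site, baseline$sex, pathway)
  L <- if (cls == "leukemia") model$latency_leukemia else model$latency_solid
  dr <- .dose_response(cf$beta, dose, model$ddref, cls,
                       model$leukemia_quadratic_theta)
  estar <- (min(e, 30) - 30) / 10
  shape <- exp(cf$gamma * estar) * (a / 60)^cf$eta
  rate <- if (pathway == "ERR") {
    lam <- stats::approx(baseline$ages, baseline$rate_by_age, xout = a)$y
    dr * shape * lam
  } else {
    dr * shape / 1e4
  }
  rate[a < e + L] <- 0
  rate
}

#' Divide a linear risk component by the DDREF
#'
#' The dose and dose-rate effectiveness factor scales acute high-dose-rate
#' epidemiology down to low-dose conditions: the linear component of a
#' solid-cancer risk is divided by it. Not applied to the leukemia quadratic
#' term.
#'
#' @param linear_component Risk value(s).
#' @param ddref Unitless divisor, `>= 1`.
#' @return `linear_component / ddref`.
#' @export
apply_ddref <- function(linear_component, ddref) {
  if (ddref < 1) .config_error("apply_ddref(): ddref must be >= 1")
  linear_component / ddref
}

#' Combine the ERR- and EAR-projected risks into one estimate
#'
#' Weighted arithmetic mean (w_err * x + w_ear * y) or weighted geometric
#' mean exp(w_err*log x + w_ear*log y). The geometric mean is defined as 0
#' when either pathway value is 0 (continuity from below). For equal inputs
#' both rules return that value; otherwise geometric <= arithmetic.
#'
#' @param lar_err,lar_ear Non-negative pathway risk values.
#' @param w_err,w_ear Weights summing to 1 (tolerance 1e-9).
#' @param rule `"weighted_geometric"` or `"weighted_arithmetic"`.
#' @return Combined risk value.
#' @export
combine_pathways <- function(lar_err, lar_ear, w_err, w_ear,
                             rule = c("weighted_geometric",
                                      "weighted_arithmetic")) {
  rule <- match.arg(rule)
  if (abs(w_err + w_ear - 1) > 1e-9)
    .config_error("combine_pathways(): weights must sum to 1")
  if (lar_err < 0 || lar_ear < 0)
    .input_error("combine_pathways(): negative pathway risk")
  if (rule == "weighted_arithmetic") {
    w_err * lar_err + w_ear * lar_ear
  } else {
    if (lar_err == 0 || lar_ear == 0) return(0)
    exp(w_err * log(lar_err) + w_ear * log(lar_ear))
  }
}

# integration grid: integer ages from ceiling(e + L) to amax
.lar_grid <- function(e, L, amax) {
  a0 <- as.integer(ceiling(e + L))
  if (a0 > amax) return(integer(0))
  a0:amax
}

.pathway_lar <- function(model, lt, baseline, e, dose, pathway) {
  cls <- .site_class(model, baseline$site)
  L <- if (cls == "leukemia") model$latency_leukemia else model$latency_solid
  ages <- .lar_grid(e, L, lt$amax)
  if (length(ages) < 2L) return(0)
  m <- excess_absolute_rate(model, baseline, pathway, dose, e, ages)
  f <- m * survival_ratio(lt, e, ages)
  pracma::trapz(ages, f)
}

#' Lifetime attributable risk from one exposure
#'
#' Integrates the excess absolute rate, weighted by the conditional
#' probability S(a)/S(e) of remaining alive and cancer-free, over attained
#' ages from e + L (L = site-class latency) to the maximum age of the life
#' table, separately for the ERR and EAR pathways, then combines the two with
#' the model's weighting rule. Annual trapezoid quadrature on integer ages;
#' the lower limit is rounded up to the next integer age.
#'
#' @param model A `risk_model_spec`.
#' @param lt A `life_table`.
#' @param baseline A `baseline_incidence` for the site and sex.
#' @param e Age at exposure (years, `>= 18`: adult cohort scope).
#' @param dose Dose in Gy, `>= 0`.
#' @return LAR per person (probability scale).
#' @export
lar <- function(model, lt, baseline, e, dose) {
  if (dose < 0) .input_error("lar(): negative dose")
  if (e < 18) .input_error("lar(): exposure age below 18 (adult cohort scope)")
  if (dose == 0) return(0)
  combine_pathways(
    .pathway_lar(model, lt, baseline, e, dose, "ERR"),
    .pathway_lar(model, lt, baseline, e, dose, "EAR"),
    w_err = model$w_err, w_ear = model$w_ear, rule = model$combination)
}

.pathway_reic <- function(model, lt, baseline, e, dose, pathway) {
  cls <- .site_class(model, baseline$site)
  L <- if (cls == "leukemia") model$latency_leukemia else model$latency_solid
  ages <- .lar_grid(e, L, lt$amax)
  if (length(ages) < 2L) return(0)
  excess <- excess_absolute_rate(model, baseline, pathway, dose, e, ages)
  # exposed-cohort survival: baseline hazard plus the excess cancer hazard
  # accumulated since exposure (it is zero inside the latency window)
  cum_excess <- pracma::cumtrapz(ages, excess)[, 1]
  s_exposed <- survival_ratio(lt, e, ages) * exp(-cum_excess)
  pracma::trapz(ages, excess * s_exposed)
}

#' Risk of exposure-induced cancer (REIC) from one exposure
#'
#' Integrates the difference between exposed and baseline incidence,
#' weighted by the exposed-cohort survival S(a|D, e) (baseline survival
#' depleted by the accumulated excess cancer hazard), over the same range as
#' [lar()]. Approaches the LAR as dose tends to 0.
#'
#' @inheritParams lar
#' @return REIC per person.
#' @export
reic <- function(model, lt, baseline, e, dose) {
  if (dose < 0) .input_error("reic(): negative dose")
  if (e < 18) .input_error("reic(): exposure age below 18 (adult cohort scope)")
  if (dose == 0) return(0)
  combine_pathways(
    .pathway_reic(model, lt, baseline, e, dose, "ERR"),
    .pathway_reic(model, lt, baseline, e, dose, "EAR"),
    w_err = model$w_err, w_ear = model$w_ear, rule = model$combination)
}
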