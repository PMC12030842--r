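#' Excess-risk pathway coefficients
#'
#' Parameters of the excess-risk functional form used by both projection
#' pathways: risk = beta * dose * exp(gamma * e*) * (a/60)^eta, where
#' e* = (min(e, 30) - 30)/10 is the age-at-exposure modifier in decades and
#' a is attained age. For the ERR pathway beta is risk per Gy
#' (multiplicative on baseline incidence); for the EAR pathway beta is excess
#' cases per 10,000 person-year-Gy.
#'
#' @param beta Risk per unit dose; `>= 0`.
#' @param gamma Per-decade age-at-exposure modifier exponent.
#' @param eta Attained-age power exponent.
#' @param pathway `"ERR"` or `"EAR"`.
#' @return An object of class `pathway_coefficients`.
#' @export
pathway_coefficients <- function(beta, gamma, eta, pathway = c("ERR", "EAR")) {
  pathway <- match.arg(pathway)
  if (beta < 0) .input_error("pathway_coefficients(): beta must be >= 0")
  if (!is.finite(gamma) || !is.finite(eta))
    .input_error("pathway_coefficients(): gamma and eta must be finite")
  structure(list(beta = beta, gamma = gamma, eta = eta, pathway = pathway),
            class = "pathway_coefficients")
}

#' Risk-model family specification
#'
#' Bundles everything that defines one lifetime-risk model family: which
#' cancer sites it covers (and for which sex), the ERR/EAR pathway weights,
#' the dose and dose-rate effectiveness factor (DDREF), minimum latency
#' periods, the rule used to combine the two projection pathways, the risk
#' measure (lifetime attributable risk or risk of exposure-induced cancer),
#' and the reporting convention of its reference-dose tables.
#'
#' @param name Model label.
#' @param sites `data.frame` with columns `site`, `sexes`
#'   (`"both"|"male"|"female"`), `class` (`"solid"|"leukemia"`).
#' @param w_ear,w_err Pathway weights; must sum to 1 (tolerance 1e-9).
#' @param ddref Dose and dose-rate effectiveness factor, `>= 1`; divides the
#'   linear dose component for solid sites.
#' @param latency_solid,latency_leukemia Minimum latency in years (defaults
#'   5 and 2).
#' @param combination `"weighted_geometric"` or `"weighted_arithmetic"`.
#' @param risk_measure `"LAR"` or `"REIC"`.
#' @param scaling Reference-table convention: `"per_100000_per_0.1Gy"`
#'   (reference dose 0.1 Gy, denominator 100,000 persons) or
#'   `"per_10000_per_Gy"` (1 Gy, 10,000 persons).
#' @param coefficients `data.frame` with columns `site`, `sex`, `pathway`,
#'   `beta`, `gamma`, `eta` covering every (site, sex, pathway) combination
#'   implied by `sites`.
#' @param leukemia_quadratic_theta Curvature coefficient (per Gy^2) of the
#'   leukemia linear-quadratic dose response dose*(beta + theta*dose),
#'   evaluated at the model's reference dose.
#' @param sex_averaged If `TRUE`, reference-dose tables report the unweighted
#'   mean of the male and female values for both-sex sites (a single
#'   estimate for both sexes); sex-specific sites keep their own sex.
#' @return An object of class `risk_model_spec`.
#' @export
risk_model_spec <- function(name, sites, w_ear, w_err, ddref,
                            latency_solid = 5, latency_leukemia = 2,
                            combination = c("weighted_geometric",
                                            "weighted_arithmetic"),
                            risk_measure = c("LAR", "REIC"),
                            scaling = c("per_100000_per_0.1Gy",
                                        "per_10000_per_Gy"),
                            coefficients,
                            leukemia_quadratic_theta = 0,
                            sex_averaged = FALSE) {
  combination <- match.arg(combination)
  risk_measure <- match.arg(risk_measure)
  scaling <- match.arg(scaling)
  if (abs(w_ear + w_err - 1) > 1e-9)
    .config_error("risk_model_spec(): pathway weights must sum to 1")
  if (ddref < 1) .config_error("risk_model_spec(): ddref must be >= 1")
  stopifnot(all(c("site", "sexes", "class") %in% names(sites)),
            all(c("site", "sex", "pathway", "beta", "gamma", "eta") %in%
                  names(coefficients)))
  if (!all(sites$sexes %in% c("both", "male", "female")))
    .config_error("risk_model_spec(): sites$sexes must be both/male/female")
  if (!all(sites$class %in% c("solid", "leukemia")))
    .config_error("risk_model_spec(): sites$class must be solid/leukemia")
  spec <- structure(list(
    name = name, sites = sites, w_ear = w_ear, w_err = w_err, ddref = ddref,
    latency_solid = latency_solid, latency_leukemia = latency_leukemia,
    combination = combination, risk_measure = risk_measure, scaling = scaling,
    coefficients = coefficients,
    leukemia_quadratic_theta = leukemia_quadratic_theta,
    sex_averaged = sex_averaged), class = "risk_model_spec")
  # every declared (site, sex, pathway) must have coefficients
  for (i in seq_len(nrow(sites))) {
    for (sex in .sexes_for(sites$sexes[i])) {
      for (pw in c("ERR", "EAR")) {
        model_coefficients(spec, sites$site[i], sex, pw)
      }
    }
  }
  spec
}

.sexes_for <- function(sexes) if (sexes == "both") c("male", "female") else sexes

#' @export
print.risk_model_spec <- function(x, ...) {
  cat(sprintf(
    "<risk_model_spec> %s: %d sites, w_ear/w_err = %.2g/%.2g, DDREF = %.2g,\n  %s, %s, %s\n",
    x$name, nrow(x$sites), x$w_ear, x$w_err, x$ddref,
    x$combination, x$risk_measure, x$scaling))
  invisible(x)
}

#' Sites a model covers for a given sex
#'
#' @param model A `risk_model_spec`.
#' @param sex `"male"` or `"female"`.
#' @return The `sites` data.frame restricted to that sex.
#' @export
covered_sites <- function(model, sex) {
  sex <- match.arg(sex, c("male", "female"))
  model$sites[model$sites$sexes %in% c("both", sex), , drop = FALSE]
}

#' Pathway coefficients for one (site, sex, pathway)
#'
#' @param model A `risk_model_spec`.
#' @param site,sex,pathway Lookup keys.
#' @return A `pathway_coefficients` object.
#' @export
model_coefficients <- function(model, site, sex, pathway) {
  cf <- model$coefficients
  row <- cf[cf$site == site & cf$sex == sex & cf$pathway == pathway, ]
  if (nrow(row) != 1L)
    .config_error(sprintf(
      "model '%s': expected exactly one coefficient row for (%s, %s, %s), found %d",
      model$name, site, sex, pathway, nrow(row)))
  pathway_coefficients(row$beta, row$gamma, row$eta, pathway)
}

.site_class <- function(model, site) {
  cls <- model$sites$class[model$sites$site == site]
  if (length(cls) != 1L)
    .coverage_error(sprintf("site '%s' not covered by model '%s'", site, model$name))
  cls
}

.site_covered <- function(model, site, sex) {
  i <- model$sites$site == site
  any(i) && model$sites$sexes[i] %in% c("both", sex)
}

# expand the shared site catalogue into a per-sex coefficient data.frame
.catalogue_coefficients <- function(cat) {
  rows <- list()
  for (i in seq_len(nrow(cat))) {
    leuk <- cat$class[i] == "leukemia"
    for (sex in .sexes_for(cat$sexes[i])) {
      rows[[length(rows) + 1L]] <- data.frame(
        site = cat$site[i], sex = sex, pathway = c("ERR", "EAR"),
        beta = c(cat$beta_err[i], cat$beta_ear[i]),
        gamma = if (leuk) c(-0.40, -0.40) else c(-0.30, -0.41),
        eta   = if (leuk) c(-1.0, 1.0)   else c(-1.4, 2.8),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Bundled illustrative model families
#'
#' Three `risk_model_spec` objects mirroring the structural differences
#' between the BEIR VII, ICRP 103 and US EPA lifetime-risk frameworks:
#' pathway weights 0.3/0.7 (EAR/ERR) for the BEIR VII-like and EPA-like
#' families versus 0.5/0.5 for the ICRP-like family; DDREF 1.5 versus 2;
#' weighted geometric combination for BEIR VII-like versus weighted
#' arithmetic for the other two; per-100,000-per-0.1 Gy reference tables for
#' BEIR VII-like versus per-10,000-per-Gy for the other two; and differing
#' site coverage (asterisk pattern of the published site tables). The
#' numeric coefficients themselves are the shared illustrative catalogue,
#' not the official publications' values.
#'
#' @return Named list with elements `beir_vii`, `icrp103`, `epa`.
#' @export
illustrative_risk_models <- function() {
  cat <- .site_catalogue()
  pick <- function(sites) {
    s <- cat[cat$site %in% sites, c("site", "sexes", "class")]
    rownames(s) <- NULL
    s
  }
  coef_for <- function(sites) {
    cf <- .catalogue_coefficients(cat)
    cf[cf$site %in% sites, , drop = FALSE]
  }
  beir_sites <- c("bladder", "breast", "colon", "liver", "lung", "ovary",
                  "prostate", "stomach", "thyroid", "uterus", "other_solid",
                  "leukemia")
  icrp_sites <- c("bladder", "breast", "colon", "esophagus", "liver", "lung",
                  "ovary", "stomach", "thyroid", "other_solid", "leukemia")
  epa_sites  <- c("bladder", "bone", "colon", "kidney", "liver", "lung",
                  "prostate", "skin", "stomach", "thyroid", "other_solid",
                  "leukemia")
  list(
    beir_vii = risk_model_spec(
      name = "BEIR VII-like", sites = pick(beir_sites),
      w_ear = 0.3, w_err = 0.7, ddref = 1.5,
      combination = "weighted_geometric", risk_measure = "LAR",
      scaling = "per_100000_per_0.1Gy",
      coefficients = coef_for(beir_sites), leukemia_quadratic_theta = 1.0),
    icrp103 = risk_model_spec(
      name = "ICRP 103-like", sites = pick(icrp_sites),
      w_ear = 0.5, w_err = 0.5, ddref = 2,
      combination = "weighted_arithmetic", risk_measure = "REIC",
      scaling = "per_10000_per_Gy",
      coefficients = coef_for(icrp_sites), leukemia_quadratic_theta = 1.0),
    epa = risk_model_spec(
      name = "US EPA-like", sites = pick(epa_sites),
      w_ear = 0.3, w_err = 0.7, ddref = 1.5,
      combination = "weighted_arithmetic", risk_measure = "LAR",
      scaling = "per_10000_per_Gy",
      coefficients = coef_for(epa_sites), leukemia_quadratic_theta = 1.0,
      sex_averaged = TRUE)
  )
}

#' Write / read a model specification as YAML
#'
#' Round-trippable serialization of a `risk_model_spec` with explicit units
#' in the field names and a schema version tag.
#'
#' @param model A `risk_model_spec`.
#' @param path File path.
#' @return `read_model_spec` returns a `risk_model_spec`;
#'   `write_model_spec` returns `path` invisibly.
#' @export
write_model_spec <- function(model, path) {
  obj <- list(
    schema = "radoncrisk/risk_model_spec/v1",
    name = model$name,
    sites = lapply(seq_len(nrow(model$sites)), function(i)
      as.list(model$sites[i, ])),
    w_ear = model$w_ear, w_err = model$w_err, ddref = model$ddref,
    latency_solid_years = model$latency_solid,
    latency_leukemia_years = model$latency_leukemia,
    combination = model$combination, risk_measure = model$risk_measure,
    scaling = model$scaling,
    leukemia_quadratic_theta_per_Gy2 = model$leukemia_quadratic_theta,
    sex_averaged = model$sex_averaged,
    coefficients = lapply(seq_len(nrow(model$coefficients)), function(i)
      as.list(model$coefficients[i, ])))
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' @rdname write_model_spec
#' @export
read_model_spec <- function(path) {
  obj <- yaml::read_yaml(path)
  if (!identical(obj$schema, "radoncrisk/risk_model_spec/v1"))
    .config_error(sprintf("unrecognised model-spec schema in '%s'", path))
  sites <- do.call(rbind, lapply(obj$sites, as.data.frame))
  coefs <- do.call(rbind, lapply(obj$coefficients, as.data.frame))
  risk_model_spec(
    name = obj$name, sites = sites, w_ear = obj$w_ear, w_err = obj$w_err,
    ddref = obj$ddref, latency_solid = obj$latency_solid_years,
    latency_leukemia = obj$latency_leukemia_years,
    combination = obj$combination, risk_measure = obj$risk_measure,
    scaling = obj$scaling, coefficients = coefs,
    leukemia_quadratic_theta = obj$leukemia_quadratic_theta_per_Gy2,
    sex_averaged = obj$sex_averaged)
}
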