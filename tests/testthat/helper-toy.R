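# Toy fixtures with closed-form survival and constant baseline incidence so
# integrals can be checked against analytic / fine-grid oracles.

toy_life_table <- function(hazard = 0.01, amax = 100)
  constant_hazard_life_table(hazard, amax)

toy_baseline <- function(site = "colon", sex = "male", rate = 0.001,
                         amax = 100)
  baseline_incidence(site, sex, 0:amax, rep(rate, amax + 1))

# single-site model; defaults make the ERR and EAR pathway LARs identical
# on the toy baseline (beta_ear = beta_err * rate * 1e4)
toy_model <- function(beta_err = 0.5, beta_ear = 5, gamma = 0, eta = 0,
                      w_ear = 0.3, w_err = 0.7, ddref = 1,
                      combination = "weighted_arithmetic",
                      risk_measure = "LAR",
                      scaling = "per_100000_per_0.1Gy",
                      theta = 0, site = "colon", class = "solid",
                      sex_averaged = FALSE) {
  sites <- data.frame(site = site, sexes = "both", class = class,
                      stringsAsFactors = FALSE)
  coefs <- expand.grid(site = site, sex = c("male", "female"),
                       pathway = c("ERR", "EAR"), stringsAsFactors = FALSE)
  coefs$beta <- ifelse(coefs$pathway == "ERR", beta_err, beta_ear)
  coefs$gamma <- gamma
  coefs$eta <- eta
  risk_model_spec("toy", sites, w_ear = w_ear, w_err = w_err, ddref = ddref,
                  combination = combination, risk_measure = risk_measure,
                  scaling = scaling, coefficients = coefs,
                  leukemia_quadratic_theta = theta,
                  sex_averaged = sex_averaged)
}

# hand-built reference-dose table for interpolation tests
manual_lar_table <- function(values, ages = c(70, 80), site = "colon",
                             sex = "male", site_class = "solid",
                             scaling = "per_100000_per_0.1Gy") {
  ref <- if (scaling == "per_100000_per_0.1Gy") 0.1 else 1
  denom <- if (scaling == "per_100000_per_0.1Gy") 1e5 else 1e4
  structure(
    data.frame(model = "manual", sex = sex, site = site,
               site_class = site_class, exposure_age = ages, lar_ref = values,
               reference_dose_Gy = ref, denominator = denom,
               stringsAsFactors = FALSE),
    scaling = scaling, model_name = "manual",
    class = c("lar_table", "data.frame"))
}

# fine-grid (0.1-year) trapezoid oracle for the toy single-pathway LAR:
# closed-form survival exp(-h (a - e)), constant baseline incidence
toy_pathway_lar_oracle <- function(beta, gamma, eta, pathway, dose, e,
                                   hazard = 0.01, rate = 0.001, ddref = 1,
                                   L = 5, amax = 100, step = 0.1) {
  a <- seq(ceiling(e + L), amax, by = step)
  estar <- (min(e, 30) - 30) / 10
  shape <- exp(gamma * estar) * (a / 60)^eta
  m <- if (pathway == "ERR") beta * dose / ddref * shape * rate
       else beta * dose / ddref * shape / 1e4
  pracma::trapz(a, m * exp(-hazard * (a - e)))
}

# same oracle for REIC: excess hazard depletes the exposed survival
toy_pathway_reic_oracle <- function(beta, gamma, eta, pathway, dose, e,
                                    hazard = 0.01, rate = 0.001, ddref = 1,
                                    L = 5, amax = 100, step = 0.1) {
  a <- seq(ceiling(e + L), amax, by = step)
  estar <- (min(e, 30) - 30) / 10
  shape <- exp(gamma * estar) * (a / 60)^eta
  excess <- if (pathway == "ERR") beta * dose / ddref * shape * rate
            else beta * dose / ddref * shape / 1e4
  cum <- pracma::cumtrapz(a, excess)[, 1]
  pracma::trapz(a, excess * exp(-hazard * (a - e)) * exp(-cum))
}

# independent enumeration oracle for the untied Friedman null distribution:
# all within-row assignments of the rank vector 1..k, untied statistic
friedman_enum_oracle_p <- function(m) {
  n <- nrow(m); k <- ncol(m)
  stopifnot(all(apply(m, 1, function(r) !anyDuplicated(r))))
  perm <- function(v) {
    if (length(v) == 1L) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (p in perm(v[-i])) out[[length(out) + 1L]] <- c(v[i], p)
    out
  }
  perms <- perm(seq_len(k))
  stat_untied <- function(ranks) {
    R <- colSums(ranks)
    12 / (n * k * (k + 1)) * sum(R^2) - 3 * n * (k + 1)
  }
  obs <- stat_untied(t(apply(m, 1, rank)))
  grid <- do.call(expand.grid, rep(list(seq_along(perms)), n))
  stats <- apply(grid, 1, function(sel) {
    ranks <- t(vapply(seq_len(n), function(i) as.numeric(perms[[sel[i]]]),
                      numeric(k)))
    stat_untied(ranks)
  })
  mean(stats >= obs - 1e-12)
}
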