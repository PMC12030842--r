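test_that("excess relative risk evaluates its closed form", {
  neutral <- pathway_coefficients(1, 0, 0, "ERR")
  expect_equal(excess_relative_risk(neutral, 0, 40, 70), 0)
  expect_equal(excess_relative_risk(neutral, 0.1, 40, 70), 0.1)
  cf <- pathway_coefficients(0.5, -0.3, -1.4, "ERR")
  # e = 20 gives e* = -1; attained age 60 neutralises the age power
  expect_equal(excess_relative_risk(cf, 0.1, 20, 60),
               0.5 * 0.1 * exp(0.3), tolerance = 1e-12)
  expect_equal(excess_relative_risk(cf, 0.1, 20, 60), 0.06749294,
               tolerance = 1e-7)
  # linear in dose
  expect_equal(excess_relative_risk(cf, 0.3, 25, 70),
               3 * excess_relative_risk(cf, 0.1, 25, 70))
  expect_error(excess_relative_risk(cf, -0.1, 20, 60),
               class = "radoncrisk_input_error")
  expect_error(excess_relative_risk(cf, 0.1, 60, 50),
               class = "radoncrisk_input_error")
})

test_that("survival ratio is a conditional survival probability", {
  lt <- toy_life_table(0.01)
  expect_equal(survival_ratio(lt, 60, 60), 1)
  expect_equal(survival_ratio(lt, 60, 80), exp(-0.2), tolerance = 1e-12)
  # direct ratio on a custom table
  s <- c(1, 0.9, 0.8, 0.5)
  lt2 <- life_table(0:3, s)
  expect_equal(survival_ratio(lt2, 2, 3), 0.625)
  # non-increasing in attained age
  r <- survival_ratio(lt, 50, 50:100)
  expect_true(all(diff(r) <= 0))
  expect_true(all(r > 0 & r <= 1))
  expect_error(survival_ratio(lt, 70, 60), class = "radoncrisk_input_error")
})

test_that("life table constructor enforces its invariants", {
  expect_error(life_table(0:2, c(0.9, 0.8, 0.7)), class = "radoncrisk_input_error")
  expect_error(life_table(0:2, c(1, 0.5, 0.6)), class = "radoncrisk_input_error")
  expect_error(life_table(c(0, 2, 3), c(1, 0.9, 0.8)), class = "radoncrisk_input_error")
  lt <- illustrative_life_table()
  expect_equal(lt$amax, 100)
  expect_equal(lt$survival[1], 1)
  expect_true(all(diff(lt$survival) <= 0))
})

test_that("excess absolute rate follows pathway definitions and latency", {
  lt <- toy_life_table()
  bl <- toy_baseline(rate = 0.001)
  # ERR = 0.2 (beta 2, neutral modifiers, dose 0.1) times lambda = 0.001
  mod <- toy_model(beta_err = 2, beta_ear = 5)
  expect_equal(excess_absolute_rate(mod, bl, "ERR", 0.1, 40, 60), 2e-4)
  expect_equal(excess_absolute_rate(mod, bl, "ERR", 0, 40, 60), 0)
  expect_equal(excess_absolute_rate(mod, bl, "EAR", 0, 40, 60), 0)
  # EAR beta is per 10^4 person-year-Gy
  expect_equal(excess_absolute_rate(mod, bl, "EAR", 0.1, 40, 60), 5 * 0.1 / 1e4)
  # within the 5-year solid latency window the excess is 0 by contract
  expect_equal(excess_absolute_rate(mod, bl, "ERR", 0.1, 60, 63), 0)
  expect_gt(excess_absolute_rate(mod, bl, "ERR", 0.1, 60, 66), 0)
  # uncovered site
  other <- toy_baseline(site = "lung")
  expect_error(excess_absolute_rate(mod, other, "ERR", 0.1, 40, 60),
               class = "radoncrisk_coverage_error")
})

test_that("leukemia uses the linear-quadratic dose response without DDREF", {
  bl <- toy_baseline(site = "leukemia", rate = 0.001)
  mod <- toy_model(beta_err = 1, beta_ear = 10, theta = 10,
                   site = "leukemia", class = "leukemia", ddref = 2)
  # dose response 0.1*(1 + 10*0.1) = 0.2 replaces beta*dose = 0.1,
  # and the DDREF divisor must not touch it
  expect_equal(excess_absolute_rate(mod, bl, "ERR", 0.1, 40, 60),
               0.2 * 0.001)
  # leukemia latency is 2 years, not 5
  expect_gt(excess_absolute_rate(mod, bl, "ERR", 0.1, 60, 63), 0)
  expect_equal(excess_absolute_rate(mod, bl, "ERR", 0.1, 60, 61.5), 0)
})

test_that("pathway combination implements both weighted means", {
  expect_equal(combine_pathways(3, 3, 0.7, 0.3, "weighted_geometric"), 3)
  expect_equal(combine_pathways(3, 3, 0.7, 0.3, "weighted_arithmetic"), 3)
  expect_equal(combine_pathways(4, 1, 0.5, 0.5, "weighted_geometric"), 2)
  expect_equal(combine_pathways(4, 1, 0.5, 0.5, "weighted_arithmetic"), 2.5)
  expect_equal(combine_pathways(8, 1, 0.7, 0.3, "weighted_geometric"),
               8^0.7, tolerance = 1e-12)
  # log-domain cross-check
  expect_equal(combine_pathways(8, 1, 0.7, 0.3, "weighted_geometric"),
               exp(0.7 * log(8) + 0.3 * log(1)), tolerance = 1e-12)
  # geometric mean at zero is 0 by continuity
  expect_equal(combine_pathways(0, 5, 0.5, 0.5, "weighted_geometric"), 0)
  expect_error(combine_pathways(1, 1, 0.6, 0.5, "weighted_geometric"),
               class = "radoncrisk_config_error")
})

test_that("weighted geometric mean never exceeds the arithmetic mean", {
  set.seed(42)
  for (i in 1:200) {
    x <- stats::rlnorm(1, 0, 1); y <- stats::rlnorm(1, 0, 1)
    w <- stats::runif(1)
    g <- combine_pathways(x, y, w, 1 - w, "weighted_geometric")
    a <- combine_pathways(x, y, w, 1 - w, "weighted_arithmetic")
    expect_lte(g, a + 1e-12)
  }
  # equality iff inputs equal
  expect_equal(combine_pathways(2.5, 2.5, 0.8, 0.2, "weighted_geometric"),
               combine_pathways(2.5, 2.5, 0.8, 0.2, "weighted_arithmetic"))
})

test_that("DDREF divides linear components", {
  expect_equal(apply_ddref(3, 1), 3)
  expect_equal(apply_ddref(3, 1.5), 2)
  expect_equal(apply_ddref(3, 2), 1.5)
  expect_error(apply_ddref(3, 0.5), class = "radoncrisk_config_error")
})

test_that("LAR of a constant integrand has the closed-form value", {
  # zero hazard: S(a)/S(e) = 1; neutral modifiers: M constant in a
  lt <- toy_life_table(hazard = 0)
  bl <- toy_baseline(rate = 0.001)
  mod <- toy_model(beta_err = 0.5, beta_ear = 5)  # equal pathways
  e <- 60; L <- 5; dose <- 0.1
  m <- 0.5 * dose * 0.001
  expect_equal(lar(mod, lt, bl, e, dose), m * (100 - e - L), tolerance = 1e-12)
  expect_equal(lar(mod, lt, bl, e, 0), 0)
  expect_error(lar(mod, lt, bl, 17, 0.1), class = "radoncrisk_input_error")
  # empty integration range: e + L beyond the table maximum
  expect_equal(lar(mod, lt, bl, 97, 0.1), 0)
})

test_that("equal pathway LARs are invariant to weights and combination rule", {
  lt <- toy_life_table(0.01)
  bl <- toy_baseline(rate = 0.001)
  base <- lar(toy_model(w_ear = 0.5, w_err = 0.5), lt, bl, 60, 0.1)
  for (w in c(0.1, 0.3, 0.7)) {
    for (rule in c("weighted_geometric", "weighted_arithmetic")) {
      mod <- toy_model(w_ear = w, w_err = 1 - w, combination = rule)
      expect_equal(lar(mod, lt, bl, 60, 0.1), base, tolerance = 1e-10)
    }
  }
})

test_that("solid-site LAR is linear in dose and scales inversely with DDREF", {
  lt <- toy_life_table(0.01)
  bl <- toy_baseline(rate = 0.001)
  mod <- toy_model(gamma = -0.3, eta = -1.4, combination = "weighted_geometric")
  base <- lar(mod, lt, bl, 55, 0.05)
  for (k in c(0.5, 2, 7))
    expect_equal(lar(mod, lt, bl, 55, k * 0.05), k * base, tolerance = 1e-10)
  mod_d <- toy_model(gamma = -0.3, eta = -1.4,
                     combination = "weighted_geometric", ddref = 1.5)
  expect_equal(lar(mod_d, lt, bl, 55, 0.05), base / 1.5, tolerance = 1e-10)
})

test_that("LAR ignores everything inside the latency window", {
  lt <- toy_life_table(0.01)
  rate <- rep(0.001, 101)
  bl <- toy_baseline(rate = 0.001)
  # inflate the baseline incidence only below e + L: LAR must not move
  rate2 <- rate; rate2[1:65] <- 50
  bl2 <- baseline_incidence("colon", "male", 0:100, rate2)
  mod <- toy_model()
  expect_equal(lar(mod, lt, bl, 60, 0.1), lar(mod, lt, bl2, 60, 0.1))
})

test_that("annual trapezoid LAR agrees with a 0.1-year quadrature oracle", {
  lt <- toy_life_table(0.01)
  bl <- toy_baseline(rate = 0.001)
  for (e in c(20, 45, 66, 80)) {
    for (pw in c("ERR", "EAR")) {
      mod1 <- toy_model(gamma = -0.3, eta = -1.4,
                        w_err = as.numeric(pw == "ERR"),
                        w_ear = as.numeric(pw == "EAR"))
      got <- lar(mod1, lt, bl, e, 0.1)
      beta <- if (pw == "ERR") 0.5 else 5
      want <- toy_pathway_lar_oracle(beta, -0.3, -1.4, pw, 0.1, e)
      expect_equal(got, want, tolerance = 5e-3)
    }
  }
})

test_that("REIC approaches LAR at low dose and matches its quadrature oracle", {
  lt <- toy_life_table(0.01)
  bl <- toy_baseline(rate = 0.001)
  mod <- toy_model(risk_measure = "REIC")
  expect_equal(reic(mod, lt, bl, 60, 0), 0)
  r <- reic(mod, lt, bl, 60, 0.1)
  l <- lar(mod, lt, bl, 60, 0.1)
  expect_lt(abs(r - l) / l, 0.01)
  # the relative gap shrinks monotonically as dose decreases
  gaps <- vapply(c(0.1, 0.05, 0.02, 0.01), function(d) {
    abs(reic(mod, lt, bl, 60, d) - lar(mod, lt, bl, 60, d)) /
      lar(mod, lt, bl, 60, d)
  }, numeric(1))
  expect_true(all(diff(gaps) < 0))
  # fine-grid oracle for the ERR pathway alone
  mod_err <- toy_model(risk_measure = "REIC", w_err = 1, w_ear = 0)
  want <- toy_pathway_reic_oracle(0.5, 0, 0, "ERR", 0.1, 60)
  expect_equal(reic(mod_err, lt, bl, 60, 0.1), want, tolerance = 5e-3)
})

test_that("reference-dose LAR interpolation is exact on grid and linear between", {
  tab <- manual_lar_table(c(10, 20))
  expect_equal(interpolate_lar(tab, "male", "colon", 70), 10)
  expect_equal(interpolate_lar(tab, "male", "colon", 80), 20)
  expect_equal(interpolate_lar(tab, "male", "colon", 75), 15)
  expect_equal(interpolate_lar(tab, "male", "colon", 73), 13)
  # clamping, no extrapolation
  expect_equal(interpolate_lar(tab, "male", "colon", 60), 10)
  expect_equal(interpolate_lar(tab, "male", "colon", 95), 20)
  expect_error(interpolate_lar(tab, "female", "colon", 75),
               class = "radoncrisk_coverage_error")
  expect_error(interpolate_lar(tab, "male", "lung", 75),
               class = "radoncrisk_coverage_error")
  # midpoint forced by linearity for arbitrary values
  tab2 <- manual_lar_table(c(3.7, 9.1))
  expect_equal(interpolate_lar(tab2, "male", "colon", 75), (3.7 + 9.1) / 2)
})

test_that("reference-dose table entries equal direct risk evaluations", {
  lt <- toy_life_table(0.01)
  bls <- list()
  bls[["colon|male"]] <- toy_baseline(sex = "male")
  bls[["colon|female"]] <- toy_baseline(sex = "female")
  mod <- toy_model(gamma = -0.3, eta = -1.4)
  tab <- build_lar_table(mod, lt, bls)
  expect_s3_class(tab, "lar_table")
  expect_equal(nrow(tab), 2 * 8)
  for (i in c(1, 5, 12)) {
    row <- tab[i, ]
    bl <- bls[[paste(row$site, row$sex, sep = "|")]]
    expect_equal(row$lar_ref,
                 lar(mod, lt, bl, row$exposure_age, 0.1) * 1e5)
  }
  expect_true(all(tab$lar_ref >= 0))
  # fine-grid oracle per entry (single-pathway model for closed forms)
  mod_err <- toy_model(gamma = -0.3, eta = -1.4, w_err = 1, w_ear = 0)
  tab_err <- build_lar_table(mod_err, lt, bls)
  male <- tab_err[tab_err$sex == "male", ]
  for (i in seq_len(nrow(male))) {
    want <- toy_pathway_lar_oracle(0.5, -0.3, -1.4, "ERR", 0.1,
                                   male$exposure_age[i]) * 1e5
    expect_equal(male$lar_ref[i], want, tolerance = 5e-3)
  }
})

test_that("an empty site list yields an empty table", {
  lt <- toy_life_table()
  mod <- toy_model()
  mod$sites <- mod$sites[0, ]
  tab <- build_lar_table(mod, lt, list())
  expect_equal(nrow(tab), 0)
})

test_that("model specs validate their configuration", {
  expect_error(toy_model(w_ear = 0.4, w_err = 0.4),
               class = "radoncrisk_config_error")
  expect_error(toy_model(ddref = 0.8), class = "radoncrisk_config_error")
  models <- illustrative_risk_models()
  expect_named(models, c("beir_vii", "icrp103", "epa"))
  expect_equal(models$beir_vii$ddref, 1.5)
  expect_equal(models$icrp103$ddref, 2)
  expect_equal(models$epa$ddref, 1.5)
  expect_equal(models$beir_vii$combination, "weighted_geometric")
  expect_equal(models$icrp103$combination, "weighted_arithmetic")
  expect_equal(c(models$icrp103$w_ear, models$icrp103$w_err), c(0.5, 0.5))
  expect_equal(c(models$beir_vii$w_ear, models$beir_vii$w_err), c(0.3, 0.7))
  expect_equal(models$beir_vii$latency_solid, 5)
  expect_equal(models$beir_vii$latency_leukemia, 2)
})

test_that("model specs and LAR tables round-trip through their file formats", {
  models <- illustrative_risk_models()
  path <- withr::local_tempfile(fileext = ".yaml")
  write_model_spec(models$icrp103, path)
  back <- read_model_spec(path)
  expect_equal(back$name, models$icrp103$name)
  expect_equal(back$w_ear, models$icrp103$w_ear)
  expect_equal(back$ddref, models$icrp103$ddref)
  expect_equal(back$sites$site, models$icrp103$sites$site)
  expect_equal(back$coefficients$beta, models$icrp103$coefficients$beta)
  lt <- toy_life_table()
  bls <- list("colon|male" = toy_baseline(), "colon|female" = toy_baseline(sex = "female"))
  tab <- build_lar_table(toy_model(), lt, bls)
  csv <- withr::local_tempfile(fileext = ".csv")
  write_lar_table(tab, csv)
  tab2 <- read_lar_table(csv)
  expect_equal(as.data.frame(tab2), as.data.frame(tab), tolerance = 1e-12)
  expect_equal(attr(tab2, "scaling"), attr(tab, "scaling"))
})
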