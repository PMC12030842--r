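.scaling_params <- function(scaling) {
  switch(scaling,
    per_100000_per_0.1Gy = list(reference_dose = 0.1, denominator = 1e5),
    per_10000_per_Gy     = list(reference_dose = 1,   denominator = 1e4),
    .config_error(sprintf("unknown scaling convention '%s'", scaling)))
}

#' Build a reference-dose LAR table for one model
#'
#' Evaluates the model's risk measure (LAR or REIC) at its reference dose for
#' every covered (sex, site) pair on a decade grid of exposure ages, scaled
#' to the model's declared denominator (per 100,000 persons per 0.1 Gy, or
#' per 10,000 persons per Gy). When the model is `sex_averaged`, both-sex
#' sites receive the unweighted mean of the male and female values.
#'
#' @param model A `risk_model_spec`.
#' @param lt A `life_table`.
#' @param baselines Named list of `baseline_incidence` objects (see
#'   [illustrative_baselines()]); must cover every covered (site, sex).
#' @param grid Exposure-age grid in years (default decades 20..90).
#' @return A `lar_table`: data.frame with columns `model`, `sex`, `site`,
#'   `site_class`, `exposure_age`, `lar_ref`, `reference_dose_Gy`,
#'   `denominator`, plus attributes `scaling` and `model_name`.
#' @export
build_lar_table <- function(model, lt, baselines, grid = seq(20, 90, by = 10)) {
  if (any(diff(grid) <= 0)) .input_error("build_lar_table(): grid must be strictly increasing")
  sp <- .scaling_params(model$scaling)
  risk_fun <- if (model$risk_measure == "REIC") reic else lar
  rows <- list()
  for (i in seq_len(nrow(model$sites))) {
    site <- model$sites$site[i]
    for (sex in .sexes_for(model$sites$sexes[i])) {
      bl <- get_baseline(baselines, site, sex)
      vals <- vapply(grid, function(e)
        risk_fun(model, lt, bl, e, sp$reference_dose) * sp$denominator,
        numeric(1))
      rows[[length(rows) + 1L]] <- data.frame(
        model = model$name, sex = sex, site = site,
        site_class = model$sites$class[i], exposure_age = grid,
        lar_ref = vals, reference_dose_Gy = sp$reference_dose,
        denominator = sp$denominator, stringsAsFactors = FALSE)
    }
  }
  tab <- if (length(rows)) do.call(rbind, rows) else
    data.frame(model = character(), sex = character(), site = character(),
               site_class = character(), exposure_age = numeric(),
               lar_ref = numeric(), reference_dose_Gy = numeric(),
               denominator = numeric(), stringsAsFactors = FALSE)
  if (isTRUE(model$sex_averaged) && nrow(tab)) {
    both <- model$sites$site[model$sites$sexes == "both"]
    for (site in both) {
      idx <- tab$site == site
      avg <- tapply(tab$lar_ref[idx], tab$exposure_age[idx], mean)
      tab$lar_ref[idx] <- avg[as.character(tab$exposure_age[idx])]
    }
  }
  rownames(tab) <- NULL
  structure(tab, scaling = model$scaling, model_name = model$name,
            class = c("lar_table", "data.frame"))
}

#' Interpolate a reference-dose LAR at an arbitrary exposure age
#'
#' Exact table value on grid points; linear interpolation between adjacent
#' decade points otherwise (e.g. age 75 is the midpoint of the 70- and
#' 80-year values). Ages outside the grid are clamped to the nearest grid
#' endpoint (no extrapolation).
#'
#' @param table A `lar_table`.
#' @param sex,site Lookup keys.
#' @param e Exposure age in years.
#' @return Reference-dose LAR value (in the table's denominator units).
#' @export
interpolate_lar <- function(table, sex, site, e) {
  rows <- table[table$sex == sex & table$site == site, , drop = FALSE]
  if (nrow(rows) == 0L)
    .coverage_error(sprintf("(%s, %s) missing from LAR table '%s'",
                            sex, site, attr(table, "model_name")))
  e <- min(max(e, min(rows$exposure_age)), max(rows$exposure_age))
  stats::approx(rows$exposure_age, rows$lar_ref, xout = e)$y
}

#' Write / read a LAR table as delimited text
#'
#' @param table A `lar_table`.
#' @param path CSV file path.
#' @return `read_lar_table` returns a `lar_table`; `write_lar_table`
#'   returns `path` invisibly.
#' @export
write_lar_table <- function(table, path) {
  utils::write.csv(as.data.frame(table), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_lar_table
#' @export
read_lar_table <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("model", "sex", "site", "site_class", "exposure_age", "lar_ref",
            "reference_dose_Gy", "denominator")
  if (!all(need %in% names(tab)))
    .input_error("read_lar_table(): missing required columns")
  scaling <- if (all(tab$reference_dose_Gy == 0.1)) "per_100000_per_0.1Gy"
             else "per_10000_per_Gy"
  structure(tab, scaling = scaling, model_name = tab$model[1],
            class = c("lar_table", "data.frame"))
}
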