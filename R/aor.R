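#' Additional oncogenic risk from a reference-dose LAR and a patient dose
#'
#' Scales a reference-dose LAR linearly by the patient's cumulative
#' effective dose (linear no-threshold), normalising every convention to the
#' per-100,000-persons scale: a per-100,000-per-0.1 Gy value is multiplied
#' by dose_Gy / 0.1, a per-10,000-per-Gy value by dose_Gy and rescaled by 10.
#' Effective dose in mSv is treated as absorbed dose in mGy (radiation
#' weighting factor 1 for X-rays).
#'
#' @param lar_ref Reference-dose LAR value, `>= 0`, in the units declared by
#'   `scaling`.
#' @param dose_msv Cumulative effective dose in mSv, `>= 0`.
#' @param scaling `"per_100000_per_0.1Gy"` or `"per_10000_per_Gy"`.
#' @return Excess cases per 100,000 persons.
#' @export
aor <- function(lar_ref, dose_msv, scaling) {
  if (any(dose_msv < 0)) .input_error("aor(): negative dose")
  if (any(lar_ref < 0)) .input_error("aor(): negative reference LAR")
  dose_gy <- dose_msv / 1000
  switch(scaling,
    per_100000_per_0.1Gy = lar_ref * dose_gy / 0.1,
    per_10000_per_Gy     = lar_ref * dose_gy * 10,
    .config_error(sprintf("unknown scaling convention '%s'", scaling)))
}

.aggregate_sites <- c("all_solid", "leukemia", "all_cancer")

#' Per-patient, per-site additional oncogenic risk under one model
#'
#' For every site the model covers for the patient's sex: interpolate the
#' reference-dose LAR at the patient's age at admission, then scale it by
#' the patient's cumulative effective dose. Appends the aggregates
#' `all_solid` (sum over solid sites), `leukemia`, and
#' `all_cancer = all_solid + leukemia`.
#'
#' @param patient One row of a patient table (`patient_id`, `sex`,
#'   `age_at_admission`, `cumulative_effective_dose_msv`).
#' @param table A `lar_table` built by [build_lar_table()].
#' @return data.frame with columns `patient_id`, `sex`, `model`, `site`,
#'   `aor_per_100000`.
#' @export
patient_model_aor <- function(patient, table) {
  scaling <- attr(table, "scaling")
  sex <- patient$sex
  rows <- unique(table[table$sex == sex, c("site", "site_class")])
  if (nrow(rows) == 0L)
    .coverage_error(sprintf("LAR table '%s' covers no sites for sex '%s'",
                            attr(table, "model_name"), sex))
  vals <- vapply(rows$site, function(site) {
    lr <- interpolate_lar(table, sex, site, patient$age_at_admission)
    aor(lr, patient$cumulative_effective_dose_msv, scaling)
  }, numeric(1))
  solid <- sum(vals[rows$site_class == "solid"])
  leuk <- sum(vals[rows$site_class == "leukemia"])
  data.frame(
    patient_id = patient$patient_id, sex = sex,
    model = attr(table, "model_name"),
    site = c(rows$site[rows$site_class == "solid"], .aggregate_sites),
    aor_per_100000 = c(vals[rows$site_class == "solid"],
                       solid, leuk, solid + leuk),
    stringsAsFactors = FALSE, row.names = NULL)
}

#' Cohort-wide AOR in long format
#'
#' Applies [patient_model_aor()] to every patient under every model table.
#'
#' @param patients Patient table (see [patient_records()]).
#' @param tables List of `lar_table` objects (one per model).
#' @return Long-format data.frame (`patient_id`, `sex`, `model`, `site`,
#'   `aor_per_100000`).
#' @export
cohort_aor <- function(patients, tables) {
  if (inherits(tables, "lar_table")) tables <- list(tables)
  out <- list()
  for (tab in tables)
    for (i in seq_len(nrow(patients)))
      out[[length(out) + 1L]] <- patient_model_aor(patients[i, ], tab)
  do.call(rbind, out)
}

#' Cohort risk summary across models and sites
#'
#' Median (IQR) of AOR per site (rows) and model (columns), the layout of a
#' published between-model site table. Sites not covered by a model are
#' marked not-estimated (`"*"`), never zero, so downstream agreement
#' statistics can exclude them.
#'
#' @param results Long-format AOR data.frame from [cohort_aor()].
#' @param sex Optional: restrict to `"male"` or `"female"`.
#' @param digits Digits in the formatted cells (default 2).
#' @return A list of class `cohort_risk_summary` with `wide` (formatted
#'   median (IQR) strings, `"*"` where not estimated) and `stats` (numeric
#'   long format: `site`, `model`, `n`, `q1`, `median`, `q3`).
#' @export
cohort_risk_summary <- function(results, sex = NULL, digits = 2) {
  if (!is.null(sex)) results <- results[results$sex == sex, , drop = FALSE]
  if (nrow(results) == 0L) .input_error("cohort_risk_summary(): no results")
  models <- unique(results$model)
  site_order <- c(sort(setdiff(unique(results$site), .aggregate_sites)),
                  intersect(.aggregate_sites, unique(results$site)))
  stats_rows <- list()
  wide <- data.frame(site = site_order, stringsAsFactors = FALSE)
  for (m in models) wide[[m]] <- "*"
  for (site in site_order) {
    for (m in models) {
      x <- results$aor_per_100000[results$site == site & results$model == m]
      if (length(x) == 0L) next
      s <- median_iqr(x)
      stats_rows[[length(stats_rows) + 1L]] <- data.frame(
        site = site, model = m, n = length(x), q1 = s[["q1"]],
        median = s[["median"]], q3 = s[["q3"]], stringsAsFactors = FALSE)
      wide[[m]][wide$site == site] <-
        sprintf("%.*f (%.*f-%.*f)", digits, s[["median"]], digits, s[["q1"]],
                digits, s[["q3"]])
    }
  }
  structure(list(wide = wide, stats = do.call(rbind, stats_rows)),
            class = "cohort_risk_summary")
}

#' @export
print.cohort_risk_summary <- function(x, ...) {
  cat("Additional oncogenic risk per 100,000, median (IQR); * = not estimated\n")
  print(x$wide, row.names = FALSE)
  invisible(x)
}

#' Write the long-format AOR table as CSV
#'
#' @param results Long-format AOR data.frame.
#' @param path File path.
#' @export
write_aor_table <- function(results, path) {
  utils::write.csv(results, path, row.names = FALSE)
  invisible(path)
}
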