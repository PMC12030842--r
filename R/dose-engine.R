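.event_types <- c("radiograph", "fluoro_ir", "ct")
.body_regions <- c("chest", "abdomen", "pelvis", "head", "neck", "limb", "spine")

#' Effective-dose conversion factors
#'
#' Per-region factors turning each modality's dose metric into an effective
#' dose in mSv: a median effective dose per radiograph, k in
#' mSv/(mGy.cm^2) for fluoroscopy/interventional dose-area product, and a
#' DLP-to-effective-dose coefficient in mSv/(mGy.cm) for CT. All factors
#' must be positive and every body region must be present.
#'
#' @param radiograph_msv Named numeric: median mSv per radiograph per region.
#' @param fluoro_k Named numeric: k per procedure region, mSv/(mGy.cm^2).
#' @param ct_k Named numeric: DLP coefficient per region, mSv/(mGy.cm).
#' @return An object of class `conversion_factors`.
#' @export
conversion_factors <- function(radiograph_msv, fluoro_k, ct_k) {
  for (nm in c("radiograph_msv", "fluoro_k", "ct_k")) {
    v <- get(nm)
    if (!all(.body_regions %in% names(v)))
      .config_error(sprintf("conversion_factors(): %s must name every region (%s)",
                            nm, paste(.body_regions, collapse = ", ")))
    if (any(v <= 0)) .config_error(sprintf("conversion_factors(): %s must be > 0", nm))
  }
  structure(list(radiograph_msv = radiograph_msv, fluoro_k = fluoro_k,
                 ct_k = ct_k), class = "conversion_factors")
}

#' Default (illustrative) conversion factors
#'
#' Order-of-magnitude-typical values for an adult patient; configurable and
#' replaceable — they are placeholders, not the literature medians of any
#' specific survey.
#'
#' @return A `conversion_factors` object.
#' @export
default_conversion_factors <- function() {
  conversion_factors(
    radiograph_msv = c(chest = 0.02, abdomen = 0.7, pelvis = 0.6, head = 0.05,
                       neck = 0.1, limb = 0.01, spine = 1.0),
    fluoro_k = c(chest = 0.0018, abdomen = 0.0026, pelvis = 0.0026,
                 head = 0.0008, neck = 0.0012, limb = 0.0006, spine = 0.0022),
    ct_k = c(chest = 0.014, abdomen = 0.015, pelvis = 0.015, head = 0.0021,
             neck = 0.0059, limb = 0.0008, spine = 0.010)
  )
}

#' Write / read conversion factors as YAML
#'
#' @param cf A `conversion_factors` object.
#' @param path File path.
#' @export
write_conversion_factors <- function(cf, path) {
  yaml::write_yaml(list(schema = "radoncrisk/conversion_factors/v1",
                        radiograph_msv = as.list(cf$radiograph_msv),
                        fluoro_k_msv_per_mgycm2 = as.list(cf$fluoro_k),
                        ct_k_msv_per_mgycm = as.list(cf$ct_k)), path)
  invisible(path)
}

#' @rdname write_conversion_factors
#' @export
read_conversion_factors <- function(path) {
  obj <- yaml::read_yaml(path)
  if (!identical(obj$schema, "radoncrisk/conversion_factors/v1"))
    .config_error(sprintf("unrecognised conversion-factor schema in '%s'", path))
  conversion_factors(unlist(obj$radiograph_msv),
                     unlist(obj$fluoro_k_msv_per_mgycm2),
                     unlist(obj$ct_k_msv_per_mgycm))
}

.event_log_columns <- c("patient_id", "sex", "age", "event_type",
                        "body_region", "dap_mgycm2", "dlp_mgycm",
                        "effective_dose_msv")

#' Read / write an exposure-event log
#'
#' One row per irradiation event with columns `patient_id, sex, age,
#' event_type, body_region, dap_mgycm2, dlp_mgycm, effective_dose_msv`;
#' empty fields where not applicable. Scout and bolus-tracking acquisitions
#' are not events and must not appear as rows.
#'
#' @param path CSV file path.
#' @param events Event-log data.frame.
#' @export
read_event_log <- function(path) {
  ev <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(.event_log_columns %in% names(ev)))
    .input_error(sprintf("event log must have columns: %s",
                         paste(.event_log_columns, collapse = ", ")))
  ev
}

#' @rdname read_event_log
#' @export
write_event_log <- function(events, path) {
  utils::write.csv(events[, .event_log_columns], path, row.names = FALSE,
                   na = "")
  invisible(path)
}

# vectorised resolution of event effective doses; collects all failures so
# the error names every offending event at once
.event_doses <- function(events, cf) {
  n <- nrow(events)
  dose <- rep(NA_real_, n)
  problems <- character(0)
  type <- events$event_type
  region <- events$body_region
  override <- if ("effective_dose_msv" %in% names(events))
    events$effective_dose_msv else rep(NA_real_, n)
  dap <- if ("dap_mgycm2" %in% names(events)) events$dap_mgycm2 else rep(NA_real_, n)
  dlp <- if ("dlp_mgycm" %in% names(events)) events$dlp_mgycm else rep(NA_real_, n)
  for (i in seq_len(n)) {
    if (!type[i] %in% .event_types) {
      problems <- c(problems, sprintf("row %d: unknown event_type '%s'", i, type[i]))
      next
    }
    if (!is.na(override[i])) {
      if (override[i] < 0) problems <- c(problems, sprintf("row %d: negative dose override", i))
      else dose[i] <- override[i]
      next
    }
    if (!region[i] %in% .body_regions) {
      problems <- c(problems, sprintf("row %d: unknown body_region '%s'", i, region[i]))
      next
    }
    dose[i] <- switch(type[i],
      radiograph = cf$radiograph_msv[[region[i]]],
      fluoro_ir = if (is.na(dap[i])) NA_real_ else {
        if (dap[i] < 0) { problems <- c(problems, sprintf("row %d: negative DAP", i)); NA_real_ }
        else cf$fluoro_k[[region[i]]] * dap[i]
      },
      ct = if (is.na(dlp[i])) NA_real_ else {
        if (dlp[i] < 0) { problems <- c(problems, sprintf("row %d: negative DLP", i)); NA_real_ }
        else cf$ct_k[[region[i]]] * dlp[i]
      })
    if (is.na(dose[i]) && type[i] == "fluoro_ir")
      problems <- c(problems, sprintf("row %d: fluoro_ir event without DAP or override", i))
    if (is.na(dose[i]) && type[i] == "ct")
      problems <- c(problems, sprintf("row %d: ct event without DLP or override", i))
  }
  if (length(problems))
    .input_error(paste0("unresolvable exposure events:\n  ",
                        paste(problems, collapse = "\n  ")))
  dose
}

#' Effective dose of a single exposure event
#'
#' Radiographs use the per-region median lookup; fluoroscopy/interventional
#' events use k x DAP; CT events use the per-region DLP coefficient (a
#' deterministic stand-in for phantom Monte Carlo organ dosimetry). A
#' precomputed `effective_dose_msv` override always wins.
#'
#' @param ev A one-row data.frame or list with the event-log fields.
#' @param cf A `conversion_factors` object.
#' @return Effective dose in mSv.
#' @export
event_effective_dose <- function(ev, cf) {
  ev <- as.data.frame(ev, stringsAsFactors = FALSE)
  for (col in c("dap_mgycm2", "dlp_mgycm", "effective_dose_msv"))
    if (!col %in% names(ev)) ev[[col]] <- NA_real_
  .event_doses(ev, cf)
}

#' Cumulative effective dose of one patient
#'
#' Sum of the effective doses of all the patient's events; 0 for an empty
#' event list; invariant under event reordering.
#'
#' @param events Event-log rows of one patient.
#' @param cf A `conversion_factors` object.
#' @return Cumulative effective dose in mSv.
#' @export
cumulative_effective_dose <- function(events, cf) {
  if (nrow(events) == 0L) return(0)
  sum(.event_doses(events, cf))
}

#' Per-patient records from an event log
#'
#' Groups an event log by patient and computes each patient's cumulative
#' effective dose.
#'
#' @param events Event-log data.frame (see [read_event_log()]).
#' @param cf A `conversion_factors` object.
#' @return data.frame with columns `patient_id`, `sex`, `age_at_admission`,
#'   `n_events`, `cumulative_effective_dose_msv`.
#' @export
patient_records <- function(events, cf) {
  if (nrow(events) == 0L) .input_error("patient_records(): empty event log")
  if (any(events$age < 18))
    .input_error("patient_records(): pediatric events present (age < 18)")
  dose <- .event_doses(events, cf)
  ids <- unique(events$patient_id)
  out <- data.frame(
    patient_id = ids,
    sex = events$sex[match(ids, events$patient_id)],
    age_at_admission = events$age[match(ids, events$patient_id)],
    n_events = as.integer(table(factor(events$patient_id, levels = ids))),
    cumulative_effective_dose_msv =
      as.numeric(rowsum(dose, factor(events$patient_id, levels = ids))),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Cohort summary of cumulative effective dose
#'
#' Median and interquartile range of the per-patient cumulative effective
#' dose, overall and by sex, under the package quantile convention (see
#' [median_iqr()]).
#'
#' @param patients data.frame as returned by [patient_records()] (or
#'   [generate_cohort()]).
#' @return A list of class `cohort_dose_summary` with elements `n`,
#'   `overall`, `male`, `female` (each `q1`/`median`/`q3` in mSv).
#' @export
cohort_dose_summary <- function(patients) {
  if (nrow(patients) == 0L) .input_error("cohort_dose_summary(): empty cohort")
  d <- patients$cumulative_effective_dose_msv
  per_sex <- function(s) {
    x <- d[patients$sex == s]
    if (length(x) == 0L) NULL else as.list(median_iqr(x))
  }
  structure(list(n = nrow(patients),
                 overall = as.list(median_iqr(d)),
                 male = per_sex("male"), female = per_sex("female")),
            class = "cohort_dose_summary")
}

#' @export
print.cohort_dose_summary <- function(x, ...) {
  cat(sprintf("Cumulative effective dose, n = %d patients\n", x$n))
  show <- function(lbl, s) if (!is.null(s))
    cat(sprintf("  %-8s median %.2f mSv (IQR %.2f-%.2f)\n",
                lbl, s$median, s$q1, s$q3))
  show("overall", x$overall); show("male", x$male); show("female", x$female)
  invisible(x)
}

#' Write a cohort dose summary as JSON
#'
#' @param summary A `cohort_dose_summary`.
#' @param path File path.
#' @export
write_cohort_summary <- function(summary, path) {
  jsonlite::write_json(unclass(summary), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
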