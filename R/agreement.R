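#' Patients-by-models risk matrix for one site
#'
#' Pivots a long-format AOR table into a subjects (patients) x raters
#' (models) matrix for one site or aggregate. Patients with any missing
#' (not-estimated) cell are excluded listwise; at least 3 complete rows and
#' 2 models are required.
#'
#' @param results Long-format AOR data.frame from [cohort_aor()].
#' @param site Site or aggregate label (e.g. `"all_cancer"`).
#' @return Numeric matrix (rownames = patient ids, colnames = models) with
#'   attribute `site`.
#' @export
risk_matrix <- function(results, site) {
  rows <- results[results$site == site, , drop = FALSE]
  if (nrow(rows) == 0L)
    .input_error(sprintf("risk_matrix(): no results for site '%s'", site))
  ids <- unique(rows$patient_id)
  models <- unique(rows$model)
  m <- matrix(NA_real_, length(ids), length(models),
              dimnames = list(ids, models))
  m[cbind(match(rows$patient_id, ids), match(rows$model, models))] <-
    rows$aor_per_100000
  m <- m[stats::complete.cases(m), , drop = FALSE]
  if (ncol(m) < 2L)
    .input_error("risk_matrix(): need at least 2 models")
  if (nrow(m) < 3L)
    .input_error("risk_matrix(): fewer than 3 complete patients after listwise exclusion")
  attr(m, "site") <- site
  m
}

# within-row mid-ranks and the tie-robust Friedman statistic
.friedman_statistic <- function(m) {
  n <- nrow(m); k <- ncol(m)
  r <- t(apply(m, 1, rank))
  colsums <- colSums(r)
  denom <- sum(r^2) - n * k * (k + 1)^2 / 4
  if (denom <= 0) return(list(statistic = 0, degenerate = TRUE))
  num <- (k - 1) * sum((colsums - n * (k + 1) / 2)^2)
  list(statistic = num / denom, degenerate = FALSE)
}

.permutations <- function(k) {
  if (k == 1L) return(matrix(1L, 1, 1))
  sub <- .permutations(k - 1L)
  do.call(rbind, lapply(seq_len(k), function(i)
    cbind(i, sub + (sub >= i))))
}

.friedman_exact_p <- function(m, observed) {
  n <- nrow(m); k <- ncol(m)
  perms <- .permutations(k)
  np <- nrow(perms)
  idx <- rep(1L, n)
  count <- 0L; total <- np^n
  repeat {
    perm_m <- t(vapply(seq_len(n), function(i) m[i, perms[idx[i], ]],
                       numeric(k)))
    s <- .friedman_statistic(perm_m)$statistic
    if (s >= observed - 1e-12) count <- count + 1L
    j <- 1L
    while (j <= n) {
      idx[j] <- idx[j] + 1L
      if (idx[j] <= np) break
      idx[j] <- 1L; j <- j + 1L
    }
    if (j > n) break
  }
  count / total
}

#' Friedman rank test across models
#'
#' Repeated-measures rank test that the k models assign systematically
#' different risk values to the same patients. Values are ranked within each
#' patient (mid-ranks for ties) and the tie-corrected statistic is referred
#' to the chi-square distribution with k - 1 degrees of freedom; for fewer
#' than 5 patients the p-value is computed by exhaustive enumeration of all
#' within-row permutations instead. A fully tied matrix (every patient's
#' values constant) yields statistic 0 and p = 1 by contract.
#'
#' @param m Numeric subjects x raters matrix (see [risk_matrix()]), n >= 3
#'   rows and k >= 2 columns.
#' @return List of class `friedman_rank_test`: `statistic`, `df`, `p_value`,
#'   `method` (`"chi-square"` or `"exact"`), `n`, `k`.
#' @export
friedman_rank_test <- function(m) {
  m <- as.matrix(m)
  n <- nrow(m); k <- ncol(m)
  if (n < 3L || k < 2L)
    .input_error("friedman_rank_test(): need n >= 3 rows and k >= 2 columns")
  st <- .friedman_statistic(m)
  if (st$degenerate)
    return(structure(list(statistic = 0, df = k - 1L, p_value = 1,
                          method = "degenerate", n = n, k = k),
                     class = "friedman_rank_test"))
  exact_feasible <- n < 5L && factorial(k)^n <= 2e5
  if (exact_feasible) {
    p <- .friedman_exact_p(m, st$statistic)
    method <- "exact"
  } else {
    p <- stats::pchisq(st$statistic, df = k - 1, lower.tail = FALSE)
    method <- "chi-square"
  }
  structure(list(statistic = st$statistic, df = k - 1L, p_value = p,
                 method = method, n = n, k = k),
            class = "friedman_rank_test")
}

#' @export
print.friedman_rank_test <- function(x, ...) {
  cat(sprintf("Friedman rank test: chi2 = %.4g, df = %d, p = %.4g (%s, n = %d)\n",
              x$statistic, x$df, x$p_value, x$method, x$n))
  invisible(x)
}

#' Agreement category of an ICC value
#'
#' Left-closed thresholds: below 0.5 poor; 0.5 to below 0.75 moderate; 0.75
#' to below 0.9 good; 0.9 and above excellent.
#'
#' @param icc Finite ICC value.
#' @return One of `"poor"`, `"moderate"`, `"good"`, `"excellent"`.
#' @export
icc_category <- function(icc) {
  if (!is.finite(icc)) .input_error("icc_category(): non-finite ICC")
  if (icc < 0.5) "poor"
  else if (icc < 0.75) "moderate"
  else if (icc < 0.9) "good"
  else "excellent"
}

#' Consistency intraclass correlation coefficient with 95% CI
#'
#' Two-way model, single measurement, consistency definition
#' (ICC(C,1) = (MS_rows - MS_error) / (MS_rows + (k-1) MS_error)), with the
#' models treated as fixed raters. The confidence interval uses the
#' F-distribution method for this ICC form. Zero between-patient variance
#' makes the coefficient undefined; the result is flagged, not an error.
#'
#' @param m Numeric subjects x raters matrix, n >= 3 rows, k >= 2 columns.
#' @param conf_level Confidence level (default 0.95).
#' @return List of class `icc_consistency`: `icc`, `ci_low`, `ci_high`,
#'   `category`, `ms_rows`, `ms_cols`, `ms_error`, `n`, `k`, `defined`.
#' @export
icc_consistency <- function(m, conf_level = 0.95) {
  m <- as.matrix(m)
  n <- nrow(m); k <- ncol(m)
  if (n < 3L || k < 2L)
    .input_error("icc_consistency(): need n >= 3 rows and k >= 2 columns")
  grand <- mean(m)
  row_means <- rowMeans(m); col_means <- colMeans(m)
  ss_rows <- k * sum((row_means - grand)^2)
  ss_cols <- n * sum((col_means - grand)^2)
  ss_total <- sum((m - grand)^2)
  ss_error <- ss_total - ss_rows - ss_cols
  ms_rows <- ss_rows / (n - 1)
  ms_cols <- ss_cols / (k - 1)
  ms_error <- ss_error / ((n - 1) * (k - 1))
  if (ms_rows <= 0 || (ms_rows == 0 && ms_error == 0))
    return(structure(list(icc = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
                          category = NA_character_, ms_rows = ms_rows,
                          ms_cols = ms_cols, ms_error = ms_error,
                          n = n, k = k, defined = FALSE),
                     class = "icc_consistency"))
  icc <- (ms_rows - ms_error) / (ms_rows + (k - 1) * ms_error)
  alpha <- 1 - conf_level
  if (ms_error == 0) {
    lo <- hi <- 1
  } else {
    fobs <- ms_rows / ms_error
    df1 <- n - 1; df2 <- (n - 1) * (k - 1)
    fl <- fobs / stats::qf(1 - alpha / 2, df1, df2)
    fu <- fobs * stats::qf(1 - alpha / 2, df2, df1)
    lo <- (fl - 1) / (fl + k - 1)
    hi <- (fu - 1) / (fu + k - 1)
  }
  structure(list(icc = icc, ci_low = lo, ci_high = hi,
                 category = icc_category(icc), ms_rows = ms_rows,
                 ms_cols = ms_cols, ms_error = ms_error, n = n, k = k,
                 defined = TRUE),
            class = "icc_consistency")
}

#' @export
print.icc_consistency <- function(x, ...) {
  if (!x$defined) cat("ICC undefined (no between-subject variance)\n")
  else cat(sprintf("ICC(C,1) = %.3f (95%% CI %.3f-%.3f), %s agreement\n",
                   x$icc, x$ci_low, x$ci_high, x$category))
  invisible(x)
}

#' Bland-Altman agreement analysis of two paired measurements
#'
#' Bias = mean(x - y); limits of agreement = bias +/- 1.96 * SD(x - y)
#' (sample SD). Also returns the per-pair (mean, difference) points for the
#' standard plot (difference on the y-axis against the pair mean on the
#' x-axis).
#'
#' @param x,y Equal-length paired numeric vectors, n >= 2.
#' @return List of class `bland_altman`: `bias`, `sd_diff`, `loa_low`,
#'   `loa_high`, `n`, `points` (data.frame `mean`, `difference`).
#' @export
bland_altman <- function(x, y) {
  if (length(x) != length(y)) .input_error("bland_altman(): unequal lengths")
  if (length(x) < 2L) .input_error("bland_altman(): need at least 2 pairs")
  d <- x - y
  bias <- mean(d)
  sdd <- stats::sd(d)
  structure(list(bias = bias, sd_diff = sdd,
                 loa_low = bias - 1.96 * sdd, loa_high = bias + 1.96 * sdd,
                 n = length(x),
                 points = data.frame(mean = (x + y) / 2, difference = d)),
            class = "bland_altman")
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf("Bland-Altman: bias = %.4g, LoA = [%.4g, %.4g], n = %d\n",
              x$bias, x$loa_low, x$loa_high, x$n))
  invisible(x)
}

#' Pearson product-moment correlation
#'
#' Thin wrapper around the standard estimator that flags the degenerate
#' zero-variance case as undefined instead of warning.
#'
#' @param x,y Numeric vectors, n >= 3, each with nonzero variance.
#' @return List: `r` (NA when undefined), `n`, `defined`.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) .input_error("pearson_r(): unequal lengths")
  if (length(x) < 3L) .input_error("pearson_r(): need at least 3 pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    return(list(r = NA_real_, n = length(x), defined = FALSE))
  list(r = stats::cor(x, y), n = length(x), defined = TRUE)
}

#' Orthogonal (total least squares) regression
#'
#' Fits the line minimising perpendicular distances (error-variance ratio
#' 1): the slope follows the principal axis of the centred 2x2 covariance
#' matrix, intercept = mean(y) - slope * mean(x). All-identical points make
#' the fit undefined; the result is flagged, not an error.
#'
#' @param x,y Numeric vectors, n >= 3.
#' @return List of class `orthogonal_regression`: `slope`, `intercept`,
#'   `n`, `defined`.
#' @export
orthogonal_regression <- function(x, y) {
  if (length(x) != length(y)) .input_error("orthogonal_regression(): unequal lengths")
  if (length(x) < 3L) .input_error("orthogonal_regression(): need at least 3 points")
  sxx <- stats::var(x); syy <- stats::var(y); sxy <- stats::cov(x, y)
  if (sxx == 0 && syy == 0)
    return(structure(list(slope = NA_real_, intercept = NA_real_,
                          n = length(x), defined = FALSE),
                     class = "orthogonal_regression"))
  if (sxy == 0) {
    # principal axis is vertical or horizontal
    slope <- if (syy > sxx) Inf else 0
  } else {
    slope <- (syy - sxx + sqrt((syy - sxx)^2 + 4 * sxy^2)) / (2 * sxy)
  }
  intercept <- if (is.finite(slope)) mean(y) - slope * mean(x) else NA_real_
  structure(list(slope = slope, intercept = intercept, n = length(x),
                 defined = TRUE),
            class = "orthogonal_regression")
}

#' @export
print.orthogonal_regression <- function(x, ...) {
  if (!x$defined) cat("Orthogonal regression undefined (degenerate points)\n")
  else cat(sprintf("Orthogonal regression: slope = %.4g, intercept = %.4g (n = %d)\n",
                   x$slope, x$intercept, x$n))
  invisible(x)
}

#' Full inter-model agreement report for one site
#'
#' Runs the whole comparison battery on a patients x models risk matrix:
#' advisory Shapiro-Wilk normality screening per model (the omnibus test is
#' always the rank-based Friedman test, as appropriate for skewed risk
#' distributions), the Friedman test, the consistency ICC with 95% CI and
#' category, and per model pair the Bland-Altman analysis, Pearson r and
#' orthogonal regression.
#'
#' @param m Risk matrix from [risk_matrix()], or a long-format AOR
#'   data.frame together with `site`.
#' @param site Site label (required when `m` is a long-format data.frame).
#' @return List of class `agreement_report`.
#' @export
agreement_report <- function(m, site = NULL) {
  if (is.data.frame(m)) {
    if (is.null(site)) .input_error("agreement_report(): site required for long-format input")
    m <- risk_matrix(m, site)
  }
  site <- site %||% attr(m, "site")
  models <- colnames(m)
  shapiro <- lapply(seq_len(ncol(m)), function(j) {
    x <- m[, j]
    if (length(unique(x)) < 3L || length(x) < 3L || length(x) > 5000L)
      return(list(model = models[j], p_value = NA_real_))
    list(model = models[j], p_value = stats::shapiro.test(x)$p.value)
  })
  pairs <- utils::combn(ncol(m), 2, simplify = FALSE)
  pairwise <- lapply(pairs, function(ij) {
    x <- m[, ij[1]]; y <- m[, ij[2]]
    ba <- bland_altman(x, y)
    orth <- orthogonal_regression(x, y)
    list(model_x = models[ij[1]], model_y = models[ij[2]],
         pearson_r = pearson_r(x, y)$r,
         ba_bias = ba$bias, ba_loa_low = ba$loa_low, ba_loa_high = ba$loa_high,
         orth_slope = orth$slope, orth_intercept = orth$intercept,
         bland_altman = ba)
  })
  structure(list(site = site, n = nrow(m), models = models,
                 shapiro = shapiro,
                 friedman = friedman_rank_test(m),
                 icc = icc_consistency(m),
                 pairwise = pairwise),
            class = "agreement_report")
}

#' @export
print.agreement_report <- function(x, ...) {
  cat(sprintf("Agreement report, site '%s' (n = %d patients, %d models)\n",
              x$site, x$n, length(x$models)))
  print(x$friedman); print(x$icc)
  for (pw in x$pairwise)
    cat(sprintf("  %s vs %s: r = %.3f, bias = %.4g, LoA [%.4g, %.4g], slope = %.3f\n",
                pw$model_x, pw$model_y, pw$pearson_r, pw$ba_bias,
                pw$ba_loa_low, pw$ba_loa_high, pw$orth_slope))
  invisible(x)
}

#' Write an agreement report as JSON
#'
#' @param report An `agreement_report`.
#' @param path File path.
#' @export
write_agreement_report <- function(report, path) {
  obj <- list(
    site = report$site, n = report$n, models = report$models,
    shapiro = report$shapiro,
    friedman = unclass(report$friedman),
    icc = unclass(report$icc)[c("icc", "ci_low", "ci_high", "category", "defined")],
    pairwise = lapply(report$pairwise, function(pw)
      pw[c("model_x", "model_y", "pearson_r", "ba_bias", "ba_loa_low",
           "ba_loa_high", "orth_slope", "orth_intercept")]))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
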