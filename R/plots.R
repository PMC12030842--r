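#' Histogram of cumulative effective dose by sex
#'
#' @param patients Patient data.frame with `sex` and
#'   `cumulative_effective_dose_msv`.
#' @param binwidth Bin width in mSv (default 10).
#' @return A ggplot object.
#' @export
plot_dose_histogram <- function(patients, binwidth = 10) {
  ggplot2::ggplot(patients,
                  ggplot2::aes(x = cumulative_effective_dose_msv,
                               fill = sex)) +
    ggplot2::geom_histogram(binwidth = binwidth, boundary = 0,
                            position = "stack", colour = "grey30") +
    ggplot2::labs(x = "Cumulative effective dose (mSv)", y = "Patients",
                  fill = NULL) +
    ggplot2::theme_minimal()
}

#' Bland-Altman plot for one model pair
#'
#' Difference against pair mean with the bias and limits of agreement as
#' horizontal lines.
#'
#' @param ba A `bland_altman` result.
#' @param title Optional plot title.
#' @return A ggplot object.
#' @export
plot_bland_altman <- function(ba, title = NULL) {
  ggplot2::ggplot(ba$points, ggplot2::aes(x = mean, y = difference)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_hline(yintercept = ba$bias, linetype = "solid") +
    ggplot2::geom_hline(yintercept = c(ba$loa_low, ba$loa_high),
                        linetype = "dashed") +
    ggplot2::labs(x = "Mean of the two model estimates",
                  y = "Difference between model estimates", title = title) +
    ggplot2::theme_minimal()
}

#' Pairwise scatter of two models' risk estimates
#'
#' Scatter of one model's per-patient risk against another's with the
#' identity line and the orthogonal-regression fit.
#'
#' @param m Risk matrix from [risk_matrix()].
#' @param model_x,model_y Column names to compare.
#' @return A ggplot object.
#' @export
plot_model_pair <- function(m, model_x, model_y) {
  df <- data.frame(x = m[, model_x], y = m[, model_y])
  orth <- orthogonal_regression(df$x, df$y)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = x, y = y)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dotted") +
    ggplot2::labs(x = model_x, y = model_y) +
    ggplot2::theme_minimal()
  if (orth$defined && is.finite(orth$slope))
    p <- p + ggplot2::geom_abline(slope = orth$slope,
                                  intercept = orth$intercept)
  p
}

utils::globalVariables(c("cumulative_effective_dose_msv", "sex",
                         "difference", "x", "y"))
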