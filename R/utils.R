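# classed conditions so callers can distinguish bad input from bad config
# from missing model coverage
.err <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "radoncrisk_error")))
}
.input_error    <- function(msg) .err(msg, "radoncrisk_input_error")
.config_error   <- function(msg) .err(msg, "radoncrisk_config_error")
.coverage_error <- function(msg) .err(msg, "radoncrisk_coverage_error")

#' Median and interquartile range under the package quantile convention
#'
#' All cohort summaries in the package use the (n+1)p percentile convention
#' (`quantile(..., type = 6)`), the method used by common clinical statistics
#' software. On three ordered values this convention returns the extremes as
#' the quartiles.
#'
#' @param x Numeric vector; `NA`s are dropped.
#' @return Named numeric vector with elements `q1`, `median`, `q3`.
#' @export
median_iqr <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) == 0L) .input_error("median_iqr(): no non-missing values")
  q <- stats::quantile(x, probs = c(0.25, 0.5, 0.75), type = 6, names = FALSE)
  c(q1 = q[1], median = q[2], q3 = q[3])
}

.fmt_median_iqr <- function(x, digits = 2) {
  s <- median_iqr(x)
  sprintf("%.*f (%.*f-%.*f)", digits, s["median"], digits, s["q1"], digits, s["q3"])
}
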