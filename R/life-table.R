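#' Life table of cancer-free survival probabilities
#'
#' A life table holds the probability S(a) of being alive and cancer-free at
#' each integer age on a grid `0..amax`. It supplies the survival weighting
#' S(a)/S(e) used when integrating excess cancer rates over the remaining
#' lifetime.
#'
#' @param ages Integer ages, a contiguous grid starting at 0.
#' @param survival Survival probabilities S(a), one per age; S(0) must be 1,
#'   values must lie in \[0, 1\] and be non-increasing.
#' @return An object of class `life_table` with fields `ages`, `survival`,
#'   `amax`.
#' @export
life_table <- function(ages, survival) {
  ages <- as.integer(ages)
  if (length(ages) != length(survival))
    .input_error("life_table(): ages and survival lengths differ")
  if (ages[1] != 0L || any(diff(ages) != 1L))
    .input_error("life_table(): ages must be a contiguous integer grid starting at 0")
  if (abs(survival[1] - 1) > 1e-12)
    .input_error("life_table(): S(0) must equal 1")
  if (any(survival < 0 | survival > 1))
    .input_error("life_table(): survival probabilities must lie in [0, 1]")
  if (any(diff(survival) > 1e-12))
    .input_error("life_table(): survival must be non-increasing")
  structure(list(ages = ages, survival = as.numeric(survival), amax = max(ages)),
            class = "life_table")
}

#' @export
print.life_table <- function(x, ...) {
  cat(sprintf("<life_table> ages 0..%d, S(%d) = %.4g\n", x$amax, x$amax,
              x$survival[length(x$survival)]))
  invisible(x)
}

#' Life table with a constant all-cause hazard
#'
#' Produces S(a) = exp(-hazard * a) on `0..amax`. Used as an analytically
#' tractable toy population: every survival ratio has the closed form
#' exp(-hazard * (a - e)).
#'
#' @param hazard Constant annual hazard (default 0.01 / year).
#' @param amax Maximum age (default 100).
#' @return A `life_table`.
#' @export
constant_hazard_life_table <- function(hazard = 0.01, amax = 100) {
  if (hazard < 0) .input_error("hazard must be non-negative")
  ages <- 0:amax
  life_table(ages, exp(-hazard * ages))
}

#' Illustrative adult life table
#'
#' A Gompertz-Makeham survival curve (hazard A*exp(B*a) + C) with parameters
#' chosen to give a life expectancy near 79 years. Illustrative only; replace
#' with a national life table for real analyses.
#'
#' @param amax Maximum age (default 100).
#' @return A `life_table`.
#' @export
illustrative_life_table <- function(amax = 100) {
  ages <- 0:amax
  A <- 3e-5; B <- 0.09; C <- 6e-4
  cumhaz <- A / B * (exp(B * ages) - 1) + C * ages
  life_table(ages, exp(-cumhaz))
}

#' Survival probability at an (possibly fractional) age
#'
#' Linear interpolation between the integer grid points of the table.
#'
#' @param lt A `life_table`.
#' @param age Age in years, within `[0, amax]`.
#' @return S(age).
#' @export
survival_at <- function(lt, age) {
  if (any(age < 0 | age > lt$amax))
    .input_error("survival_at(): age outside the life-table grid")
  stats::approx(lt$ages, lt$survival, xout = age)$y
}

#' Conditional survival ratio S(a)/S(e)
#'
#' The probability that a person alive and cancer-free at age `e` is still
#' alive and cancer-free at attained age `a`.
#'
#' @param lt A `life_table`.
#' @param e Age at exposure (years), `e <= a`.
#' @param a Attained age (years), `a <= amax`.
#' @return A probability in (0, 1].
#' @export
survival_ratio <- function(lt, e, a) {
  if (any(a < e)) .input_error("survival_ratio(): attained age below exposure age")
  se <- survival_at(lt, e)
  if (any(se <= 0)) .input_error("survival_ratio(): S(e) = 0, degenerate cohort")
  survival_at(lt, a) / se
}
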