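#' Group-fairness and global-fit metrics
#'
#' Risk-adjustment formulas are evaluated here with a suite of group
#' residual-error measures plus global \eqn{R^2}. Throughout, `a` indicates
#' membership in the protected (potentially undercompensated) group `g`;
#' its complement is `gc`.
#'
#' Two residual orientations are in play in this literature and both are kept
#' deliberately: the *metrics* `net_compensation()` and
#' `mean_residual_difference()` average \eqn{\hat Y - Y}, so that a negative
#' value means undercompensation, while the estimator penalties work with
#' \eqn{Y - \hat Y}. Use [residual_orientation()] as a reminder.
#'
#' @param y Numeric vector of observed outcomes (currency units).
#' @param y_hat Numeric vector of predictions, same length as `y`.
#' @param a Binary (0/1) protected-group indicator, same length as `y`.
#' @param which_group `"g"` (members, `a == 1`) or `"gc"` (complement).
#'
#' @return `net_compensation()` and `mean_residual_difference()` return a
#'   single currency value; `predictive_ratio()` a ratio; `fair_covariance()`
#'   a covariance in currency times indicator units; `r_squared()` a percent.
#' @name fairness-metrics
NULL

validate_evaluation_input <- function(y, y_hat, a) {
  n <- length(y)
  if (length(y_hat) != n || length(a) != n) {
    abort("`y`, `y_hat` and `a` must have identical length.")
  }
  if (n < 2) abort("Need at least two observations.")
  if (anyNA(y) || anyNA(y_hat) || anyNA(a)) abort("Missing values are not allowed.")
  if (!all(a %in% c(0, 1))) abort("`a` must contain only 0 and 1.")
  if (sum(a == 1) == 0) abort("Protected group g is empty.")
  if (sum(a == 0) == 0) abort("Complement group gc is empty.")
  invisible(TRUE)
}

group_index <- function(a, which_group) {
  which_group <- match.arg(which_group, c("g", "gc"))
  if (which_group == "g") a == 1 else a == 0
}

#' @describeIn fairness-metrics Group mean of (predicted - observed); negative
#'   values mean the group is undercompensated.
#' @export
net_compensation <- function(y, y_hat, a, which_group = c("g", "gc")) {
  validate_evaluation_input(y, y_hat, a)
  idx <- group_index(a, which_group)
  mean(y_hat[idx] - y[idx])
}

#' @describeIn fairness-metrics Net compensation of g minus net compensation
#'   of gc; zero indicates parity of mean residuals across groups.
#' @export
mean_residual_difference <- function(y, y_hat, a) {
  net_compensation(y, y_hat, a, "g") - net_compensation(y, y_hat, a, "gc")
}

#' @describeIn fairness-metrics Group sum of predictions over group sum of
#'   observations; 1 means exact group-level compensation, below 1
#'   undercompensation.
#' @export
predictive_ratio <- function(y, y_hat, a, which_group = c("g", "gc")) {
  validate_evaluation_input(y, y_hat, a)
  idx <- group_index(a, which_group)
  denom <- sum(y[idx])
  if (denom == 0) {
    abort(paste0("Observed outcome sum for group `",
                 match.arg(which_group, c("g", "gc")),
                 "` is zero; predictive ratio undefined."))
  }
  sum(y_hat[idx]) / denom
}

#' @describeIn fairness-metrics Empirical covariance (population divisor N)
#'   between the group indicator and the residual (Y - Yhat). Positive values
#'   signal systematically high residuals - undercompensation - for g.
#' @export
fair_covariance <- function(y, y_hat, a) {
  validate_evaluation_input(y, y_hat, a)
  # both-groups-non-empty check above already excludes constant a
  r <- y - y_hat
  mean((a - mean(a)) * (r - mean(r)))
}

#' @describeIn fairness-metrics Fair covariance divided by a reference value
#'   `c_star` (the covariance under the OLS fit); equals 1 for the OLS
#'   predictions themselves, 0 when the covariance is removed, and goes
#'   negative when the group flips into overcompensation.
#' @param c_star Reference covariance, typically from the OLS fit
#'   (`c_star` attribute of [fit_ols()] or [cross_validate()] results).
#' @export
scaled_fair_covariance <- function(y, y_hat, a, c_star) {
  if (!is.numeric(c_star) || length(c_star) != 1 || is.na(c_star)) {
    abort("`c_star` must be a single number.")
  }
  if (c_star == 0) {
    abort("`c_star` is zero: the reference model is already exactly fair, scaling is undefined.")
  }
  fair_covariance(y, y_hat, a) / c_star
}

#' @describeIn fairness-metrics Percent of outcome variance explained,
#'   \eqn{100 (1 - SSE/SST)}; can be negative for poor out-of-sample
#'   predictions.
#' @export
r_squared <- function(y, y_hat) {
  if (length(y) != length(y_hat)) abort("`y` and `y_hat` must have identical length.")
  if (anyNA(y) || anyNA(y_hat)) abort("Missing values are not allowed.")
  sst <- sum((y - mean(y))^2)
  if (sst == 0) abort("`y` has zero variance; R-squared undefined.")
  100 * (1 - sum((y - y_hat)^2) / sst)
}

#' One-row fairness report for a prediction vector
#'
#' Assembles the full metric suite for one set of predictions into a one-row
#' tibble with the fixed column layout used throughout the package and in the
#' CSV reports: `R2` (percent), `PR_g`, `PR_gc` (predictive ratios), `NC_g`,
#' `NC_gc` (net compensation, currency), `MRD` (mean residual difference),
#' `FairCov` and, when a reference `c_star` is supplied, `ScaledFairCov`.
#'
#' @inheritParams fairness-metrics
#' @param c_star Optional reference covariance for the scaled fair covariance
#'   (use the OLS value on the same prediction protocol). `NULL` leaves
#'   `ScaledFairCov` as `NA`.
#' @return A one-row tibble.
#' @examples
#' y <- c(10, 10, 0, 0); y_hat <- c(8, 8, 1, 1); a <- c(1, 1, 0, 0)
#' fairness_report(y, y_hat, a)
#' @export
fairness_report <- function(y, y_hat, a, c_star = NULL) {
  validate_evaluation_input(y, y_hat, a)
  tibble(
    R2 = r_squared(y, y_hat),
    PR_g = predictive_ratio(y, y_hat, a, "g"),
    PR_gc = predictive_ratio(y, y_hat, a, "gc"),
    NC_g = net_compensation(y, y_hat, a, "g"),
    NC_gc = net_compensation(y, y_hat, a, "gc"),
    MRD = mean_residual_difference(y, y_hat, a),
    FairCov = fair_covariance(y, y_hat, a),
    ScaledFairCov = if (is.null(c_star)) NA_real_ else
      scaled_fair_covariance(y, y_hat, a, c_star),
    c_star = if (is.null(c_star)) NA_real_ else c_star
  )
}

#' State the residual orientation used by each part of the package
#'
#' The fairness *metrics* average \eqn{\hat Y - Y} (negative = the group is
#' paid too little), while the *estimator* constraint and penalty terms are
#' written on \eqn{Y - \hat Y} (positive = the group's spending is
#' underpredicted). The two differ only by sign but silent mix-ups are a
#' classic source of bugs; this helper returns the residuals in a named
#' orientation.
#'
#' @inheritParams fairness-metrics
#' @param orientation `"prediction_minus_observed"` (metric convention) or
#'   `"observed_minus_prediction"` (estimator convention).
#' @return Numeric residual vector in the requested orientation.
#' @export
residual_orientation <- function(y, y_hat,
                                 orientation = c("prediction_minus_observed",
                                                 "observed_minus_prediction")) {
  orientation <- match.arg(orientation)
  if (orientation == "prediction_minus_observed") y_hat - y else y - y_hat
}
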