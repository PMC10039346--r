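#' @name trend
#' @title Lowess trajectory smoothing and trend-onset classification
#'
#' @description
#' All of an analyte's measurements (not only the latest) are pooled per arm
#' as z-scores against days before the index date (a negative axis: -1000 is
#' 1000 days before the event). Each arm is smoothed with robust locally
#' weighted regression (lowess, R defaults: span 2/3, 3 robustifying
#' iterations), the two curves are aligned on a daily grid over their common
#' range, and a trend is declared from the earliest day after which the case
#' curve stays strictly on one side of the control curve through the index
#' date. A trend is significant when the case curve changes by more than
#' `delta_threshold` z-units over the trend and is monotone throughout it.
NULL

#' Robust locally weighted scatterplot smoothing
#'
#' Thin wrapper around [stats::lowess()] with the classical defaults (span
#' 2/3, 3 robustifying iterations) and no delta-based point skipping, so
#' every distinct x receives its own local fit.
#'
#' @param x Numeric predictor (days before index, negative axis).
#' @param y Numeric response (z-scores).
#' @param span Fraction of points in each local window (default 2/3).
#' @param robust_iters Robustifying (bisquare) iterations (default 3).
#' @return data.frame with `x` (sorted) and `fitted`.
#' @export
lowess_fit <- function(x, y, span = 2 / 3, robust_iters = 3) {
  stopifnot(length(x) == length(y))
  if (length(x) < 20) stop("lowess_fit requires at least 20 points")
  if (length(unique(x)) < 3) stop("too few distinct x values for the span window")
  fit <- stats::lowess(x, y, f = span, iter = robust_iters, delta = 0)
  data.frame(x = fit$x, fitted = fit$y)
}

#' Align two smoothed curves on a common daily grid
#'
#' Linear interpolation of both curves onto the intersection of their x
#' ranges; extrapolation is never performed.
#'
#' @param case_curve,control_curve data.frames with `x`, `fitted`.
#' @param step Grid step in days (default 1).
#' @return data.frame with `x`, `case`, `control`.
#' @export
align_to_grid <- function(case_curve, control_curve, step = 1) {
  dedupe <- function(cv) {
    # lowess emits one fitted value per input point; collapse tied x by mean
    if (anyDuplicated(cv$x)) {
      y <- tapply(cv$fitted, cv$x, mean)
      cv <- data.frame(x = as.numeric(names(y)), fitted = as.numeric(y))
    }
    cv
  }
  case_curve <- dedupe(case_curve)
  control_curve <- dedupe(control_curve)
  lo <- max(min(case_curve$x), min(control_curve$x))
  hi <- min(max(case_curve$x), max(control_curve$x))
  if (lo > hi) stop("curves do not overlap in x")
  grid <- seq(lo, hi, by = step)
  if (grid[length(grid)] < hi) grid <- c(grid, hi)
  data.frame(
    x = grid,
    case = stats::approx(case_curve$x, case_curve$fitted, xout = grid)$y,
    control = stats::approx(control_curve$x, control_curve$fitted,
                            xout = grid)$y)
}

#' Classify trend onset, direction, significance and confidence
#'
#' The trend start is the earliest grid time from which the case-control
#' difference keeps a constant nonzero sign through the index date. The
#' direction is the sign of the case curve's net change over the trend. The
#' trend is significant when that change exceeds `delta_threshold` in
#' magnitude and the case curve is monotone over the trend (per-step
#' violations beyond `eps` allowed at no more than 2% of steps). Confidence
#' is `higher50` when the sign separation holds with margin `margin` on at
#' least 90% of the trend, else `lower50`.
#'
#' @param grid Aligned grid from [align_to_grid()].
#' @param delta_threshold Minimum |z change| for significance (default 0.1).
#' @param eps Monotonicity tolerance per step, z-units (default 0.005).
#' @param margin Separation margin for confidence, z-units (default 0.02).
#' @return List: `start_time` (grid time, negative days; NA when no trend),
#'   `direction` (`positive`/`negative`/`none`), `significant`, `confidence`
#'   (`lower50`/`higher50`), `delta_z`.
#' @export
detect_trend <- function(grid, delta_threshold = 0.1, eps = 0.005,
                         margin = 0.02) {
  d <- grid$case - grid$control
  n <- length(d)
  none <- list(start_time = NA_real_, direction = "none", significant = FALSE,
               confidence = "lower50", delta_z = 0)
  if (n < 2 || d[n] == 0 || !is.finite(d[n])) return(none)
  s <- sign(d[n])
  i <- n
  while (i > 1 && is.finite(d[i - 1]) && sign(d[i - 1]) == s) i <- i - 1
  if (i == n) return(none)  # a single-point suffix is not a trend
  run <- i:n
  delta_z <- grid$case[n] - grid$case[i]
  direction <- if (delta_z > 0) "positive" else if (delta_z < 0) "negative" else "none"
  steps <- diff(grid$case[run])
  mono <- if (direction == "positive") mean(steps < -eps) <= 0.02
          else if (direction == "negative") mean(steps > eps) <= 0.02
          else FALSE
  significant <- direction != "none" && abs(delta_z) > delta_threshold && mono
  confidence <- if (mean(abs(d[run]) >= margin) >= 0.9) "higher50" else "lower50"
  list(start_time = grid$x[i], direction = direction,
       significant = significant, confidence = confidence, delta_z = delta_z)
}

#' Full trend analysis for one adjusted analyte series
#'
#' Pools all adjusted observations per arm, smooths each with
#' [lowess_fit()], aligns the curves and classifies the trend.
#'
#' @param adjusted Adjusted series data.frame with `z`, `days_before` and
#'   `role` (`case`/`control`) columns.
#' @param delta_threshold,eps,margin Passed to [detect_trend()].
#' @param min_points Minimum observations per arm (default 20).
#' @return A [detect_trend()] result, or `NULL` when either arm has fewer
#'   than `min_points` observations.
#' @export
trend_for_series <- function(adjusted, delta_threshold = 0.1, eps = 0.005,
                             margin = 0.02, min_points = 20) {
  ca <- adjusted[adjusted$role == "case", , drop = FALSE]
  co <- adjusted[adjusted$role == "control", , drop = FALSE]
  if (nrow(ca) < min_points || nrow(co) < min_points) return(NULL)
  case_curve <- lowess_fit(-ca$days_before, ca$z)
  control_curve <- lowess_fit(-co$days_before, co$z)
  grid <- align_to_grid(case_curve, control_curve)
  detect_trend(grid, delta_threshold = delta_threshold, eps = eps,
               margin = margin)
}
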