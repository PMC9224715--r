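# Prediction-quality metrics. The headline score is the average relative
# rooted mean square error: each repeated experiment contributes its
# validation RMSE in meters, the experiment mean is divided by the cohort
# mean measured distance, making scores comparable across datasets and use
# cases. Reliability between measured and predicted distances is quantified
# by a two-way random-effects, absolute-agreement, single-measure
# intraclass correlation.

#' Average relative rooted mean square error
#'
#' `mean(rmse) / dist_avg`, together with the standard deviation of the
#' per-experiment relative RMSEs. `dist_avg` is the mean measured distance
#' over the full cohort, a single global scaling factor. Failed (diverged)
#' runs are excluded from the average but counted; when more runs failed
#' than succeeded the configuration is scored at the saturation value 1
#' (100% relative error).
#'
#' @param rmse Numeric vector of per-experiment validation RMSEs (meters),
#'   failed runs already removed.
#' @param dist_avg Positive cohort mean measured distance (meters).
#' @param n_failed Number of excluded failed runs for this configuration.
#' @return One-row tibble: `msearr`, `msearr_sd`, `n_exp` (usable), `n_failed`.
#' @export
#' @examples
#' msearr(c(10, 20), dist_avg = 150)  # msearr = 0.1
msearr <- function(rmse, dist_avg, n_failed = 0L) {
  if (!is.numeric(dist_avg) || length(dist_avg) != 1L || dist_avg <= 0) {
    abort_config("`dist_avg` must be a single positive number")
  }
  rmse <- rmse[is.finite(rmse)]
  if (any(rmse < 0)) abort_data("RMSE values must be non-negative")
  n_usable <- length(rmse)
  if (n_usable == 0L || n_failed > n_usable) {
    return(tibble(msearr = 1, msearr_sd = NA_real_,
                  n_exp = n_usable, n_failed = as.integer(n_failed)))
  }
  rel <- rmse / dist_avg
  tibble(msearr = mean(rel),
         msearr_sd = if (n_usable > 1) sd(rel) else NA_real_,
         n_exp = n_usable, n_failed = as.integer(n_failed))
}

#' Centered moving average
#'
#' Window of odd size (default 3) centered on each point; at the series
#' edges the window truncates to the available points, so the output has
#' the same length as the input.
#'
#' @param x Numeric series (ordered).
#' @param window Positive odd integer window size.
#' @return Smoothed numeric vector, `length(x)` long.
#' @export
#' @examples
#' moving_average(c(1, 2, 3, 4, 5))  # 1.5 2 3 4 4.5
moving_average <- function(x, window = 3L) {
  if (length(x) == 0) abort_data("series is empty")
  if (window < 1 || window %% 2 == 0) {
    abort_config("`window` must be a positive odd integer")
  }
  half <- (window - 1L) %/% 2L
  n <- length(x)
  vapply(seq_len(n), function(i) {
    mean(x[max(1L, i - half):min(n, i + half)])
  }, numeric(1))
}

#' Absolute-error distribution of predictions
#'
#' Fractions of predictions with absolute error below 15 m, between 15 and
#' 25 m, and above 25 m (outliers), plus a signed-error histogram (5 m
#' bins) and the prediction/measurement scatter pairs. The three fractions
#' always partition the data.
#'
#' @param predictions,actuals Equal-length numeric vectors (meters).
#' @return A list of class `error_distribution`: `fractions` (named length-3
#'   vector), `histogram` (tibble `mid`, `count`), `scatter` (tibble
#'   `measured`, `predicted`, `error`).
#' @export
error_distribution <- function(predictions, actuals) {
  if (length(predictions) == 0) abort_data("empty prediction vector")
  if (length(predictions) != length(actuals)) {
    abort_config("predictions and actuals must have equal length")
  }
  err <- predictions - actuals
  a <- abs(err)
  fractions <- c(within_15m = mean(a < 15),
                 between_15_25m = mean(a >= 15 & a <= 25),
                 above_25m = mean(a > 25))
  lo <- floor(min(err) / 5) * 5
  hi <- ceiling(max(err) / 5) * 5
  if (hi <= lo) hi <- lo + 5
  h <- graphics::hist(err, breaks = seq(lo, hi, by = 5), plot = FALSE)
  structure(list(
    fractions = fractions,
    histogram = tibble(mid = h$mids, count = h$counts),
    scatter = tibble(measured = actuals, predicted = predictions,
                     error = err)),
    class = "error_distribution")
}

#' Per-patient absolute and relative differences
#'
#' Both reported as absolute values; the relative difference is scaled by
#' the measured distance.
#'
#' @param measured Strictly positive measured distances (meters).
#' @param predicted Predicted distances (meters).
#' @return Tibble with `measured`, `predicted`, `abs_diff` (m) and
#'   `rel_diff` (fraction of the measured distance).
#' @export
relative_differences <- function(measured, predicted) {
  if (length(measured) != length(predicted)) {
    abort_config("measured and predicted must have equal length")
  }
  if (any(measured <= 0)) abort_data("measured distances must be positive")
  tibble(measured = measured, predicted = predicted,
         abs_diff = abs(predicted - measured),
         rel_diff = abs(predicted - measured) / measured)
}

#' @describeIn relative_differences Mean +/- SD summary of both differences.
#' @param diffs Output of `relative_differences()`.
#' @export
summarise_differences <- function(diffs) {
  tibble(abs_mean = mean(diffs$abs_diff), abs_sd = sd(diffs$abs_diff),
         rel_mean = mean(diffs$rel_diff), rel_sd = sd(diffs$rel_diff))
}

#' Intraclass correlation between measured and predicted distances
#'
#' Two-way random-effects, absolute-agreement, single-measure ICC —
#' ICC(A,1) in McGraw & Wong's taxonomy, ICC(2,1) in Shrout & Fleiss's —
#' computed from the two-way ANOVA mean squares of the subject-by-method
#' layout, with the standard F-based 95% confidence interval.
#'
#' @param measured,predicted Equal-length paired numeric vectors (>= 3
#'   pairs, non-constant).
#' @param conf_level Confidence level for the interval (default 0.95).
#' @return One-row tibble: `icc`, `conf_low`, `conf_high`, `ms_rows`,
#'   `ms_cols`, `ms_error`, `n`.
#' @export
icc_agreement <- function(measured, predicted, conf_level = 0.95) {
  if (length(measured) != length(predicted)) {
    abort_config("measured and predicted must have equal length")
  }
  n <- length(measured)
  if (n < 3) abort_data("at least 3 paired observations are required")
  Y <- cbind(measured, predicted)
  k <- 2L
  grand <- mean(Y)
  row_means <- rowMeans(Y)
  col_means <- colMeans(Y)
  ss_rows <- k * sum((row_means - grand)^2)
  ss_cols <- n * sum((col_means - grand)^2)
  ss_total <- sum((Y - grand)^2)
  ss_err <- ss_total - ss_rows - ss_cols
  msr <- ss_rows / (n - 1)
  msc <- ss_cols / (k - 1)
  mse <- ss_err / ((n - 1) * (k - 1))
  denom <- msr + (k - 1) * mse + k / n * (msc - mse)
  if (!is.finite(denom) || denom <= 0 || msr == 0) {
    abort_data("ICC is undefined for (near-)constant inputs")
  }
  est <- (msr - mse) / denom

  if (mse == 0) {
    # perfect agreement: the interval degenerates to the estimate
    return(tibble(icc = est, conf_low = est, conf_high = est,
                  ms_rows = msr, ms_cols = msc, ms_error = mse, n = n))
  }
  alpha <- 1 - conf_level
  # F-based interval for ICC(A,1) (McGraw & Wong 1996).
  a <- k * est / (n * (1 - est))
  b <- 1 + k * est * (n - 1) / (n * (1 - est))
  v <- (a * msc + b * mse)^2 /
    ((a * msc)^2 / (k - 1) + (b * mse)^2 / ((n - 1) * (k - 1)))
  f_l <- qf(1 - alpha / 2, n - 1, v)
  f_u <- qf(1 - alpha / 2, v, n - 1)
  lower <- n * (msr - f_l * mse) /
    (f_l * (k * msc + (k * n - n - k) * mse) + n * msr)
  upper <- n * (f_u * msr - mse) /
    (k * msc + (k * n - n - k) * mse + n * f_u * msr)
  tibble(icc = est,
         conf_low = min(lower, est), conf_high = max(upper, est),
         ms_rows = msr, ms_cols = msc, ms_error = mse, n = n)
}

#' @export
print.error_distribution <- function(x, ...) {
  f <- x$fractions
  cat(sprintf(
    "<error_distribution> |err| < 15 m: %.1f%%; 15-25 m: %.1f%%; > 25 m: %.1f%% (n = %d)\n",
    100 * f[1], 100 * f[2], 100 * f[3], nrow(x$scatter)))
  invisible(x)
}
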