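# Train-only-fitted preprocessing: mean imputation, winsorizing at
# mean +/- k*SD, and per-feature z-scoring. The target stays in meters —
# prediction errors are reported on the measured scale and the quality
# metric is made relative by the cohort mean distance, not by scaling the
# target.

#' Seeded train/validation split
#'
#' Randomly partitions a feature table into a training and a validation set.
#' The training size is `round(train_fraction * n)` with halves rounded away
#' from zero; the same seed always yields the same index sets.
#'
#' @param ft A [as_feature_table()] object.
#' @param train_fraction Proportion of rows assigned to training, in (0, 1).
#' @param seed Integer seed controlling the permutation.
#' @return A list with `feature_table` elements `train` and `validation`.
#' @export
#' @examples
#' ft <- simulate_gait_cohort(n_patients = 50, n_features = 6, seed = 1)
#' sp <- split_feature_table(ft, train_fraction = 0.8, seed = 7)
#' nrow(sp$train)
split_feature_table <- function(ft, train_fraction = 0.8, seed = 1L) {
  if (!is.numeric(train_fraction) || train_fraction <= 0 || train_fraction >= 1) {
    abort_config("`train_fraction` must lie strictly between 0 and 1")
  }
  n <- nrow(ft)
  if (n < 5) abort_data("at least 5 rows are required to split")
  n_train <- as.integer(round_half_away(train_fraction * n))
  n_train <- max(1L, min(n - 1L, n_train))
  idx <- withr::with_seed(seed, sample.int(n, n_train))
  list(train = restore_feature_table(ft[sort(idx), ], ft),
       validation = restore_feature_table(ft[sort(setdiff(seq_len(n), idx)), ], ft))
}

#' Fit the preprocessing model on training rows
#'
#' Per feature: the imputation value is the mean of the observed training
#' entries; winsorizing bounds are that mean +/- `outlier_k` sample standard
#' deviations of the observed entries; centering and scaling constants are
#' computed from the imputed, clipped training values. Constant features get
#' scale 1. Nothing from validation rows enters the fit.
#'
#' @param train Training `feature_table`.
#' @param outlier_k Clip width in standard deviations (default 4).
#' @return A `gait_preprocess` object; see [tidy.gait_preprocess()].
#' @export
fit_preprocess <- function(train, outlier_k = 4) {
  if (nrow(train) == 0) abort_data("training table is empty")
  if (!is.numeric(outlier_k) || outlier_k <= 0) {
    abort_config("`outlier_k` must be positive")
  }
  feats <- feature_names(train)
  stats_tbl <- purrr::map_dfr(feats, function(f) {
    v <- train[[f]]
    obs <- v[!is.na(v)]
    if (length(obs) == 0) {
      abort_data(sprintf("feature '%s' has no observed training values", f))
    }
    m <- mean(obs)
    s <- if (length(obs) > 1) sd(obs) else 0
    lower <- m - outlier_k * s
    upper <- m + outlier_k * s
    filled <- ifelse(is.na(v), m, v)
    clipped <- pmin(pmax(filled, lower), upper)
    center <- mean(clipped)
    scale <- sd(clipped)
    if (!is.finite(scale) || scale == 0) scale <- 1
    tibble(feature = f, impute = m, lower = lower, upper = upper,
           center = center, scale = scale)
  })
  structure(list(stats = stats_tbl, outlier_k = outlier_k,
                 target = target_name(train)),
            class = "gait_preprocess")
}

#' Apply a fitted preprocessing model
#'
#' Imputes missing feature cells, winsorizes, then standardizes each feature
#' with the training-fitted constants. The target column passes through
#' unchanged (the network regresses meters directly).
#'
#' @param prep A `gait_preprocess` from [fit_preprocess()].
#' @param ft A `feature_table` whose feature columns match the fit.
#' @return The transformed `feature_table`.
#' @export
apply_preprocess <- function(prep, ft) {
  stopifnot(inherits(prep, "gait_preprocess"))
  feats <- feature_names(ft)
  if (!identical(sort(feats), sort(prep$stats$feature))) {
    abort_config("feature columns do not match the fitted preprocessing model")
  }
  out <- ft
  st <- prep$stats
  for (i in seq_len(nrow(st))) {
    f <- st$feature[i]
    v <- out[[f]]
    v <- ifelse(is.na(v), st$impute[i], v)
    v <- pmin(pmax(v, st$lower[i]), st$upper[i])
    out[[f]] <- (v - st$center[i]) / st$scale[i]
  }
  restore_feature_table(out, ft)
}

#' @describeIn fit_preprocess Per-feature imputation, clipping, and scaling
#'   constants as a tibble.
#' @param x A `gait_preprocess` object.
#' @param ... Unused.
#' @export
tidy.gait_preprocess <- function(x, ...) {
  x$stats
}

#' @export
print.gait_preprocess <- function(x, ...) {
  cat(sprintf("<gait_preprocess> %d features, outlier_k = %g\n",
              nrow(x$stats), x$outlier_k))
  invisible(x)
}
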