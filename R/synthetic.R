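# Synthetic gait-feature cohorts. A single latent "walking ability" factor
# per patient drives both the measured 2-minute-walk distance and a small
# informative subset of features (cadence-, speed- and stride-like), so a
# regressor that works must recover a latent-linear signal through noisy,
# partially missing, occasionally corrupted columns — the weakest structure
# the study data could have, and hence the most honest recovery testbed.
# Nuisance features share a low-rank correlation to mimic the redundancy of
# left/right/aggregate sensor columns. Everything is seed-deterministic.

informative_templates <- function() {
  tibble(
    name = c("Lower Limb - Cadence R (steps/min)",
             "Lower Limb - Gait Speed R (m/s)",
             "Lower Limb - Stride Length L (m)",
             "Lower Limb - Cadence L (steps/min)",
             "Lower Limb - Gait Speed L (m/s)"),
    center = c(105, 1.05, 1.15, 105, 1.05),
    scale = c(14, 0.28, 0.22, 14, 0.28))
}

#' Simulate a gait-feature cohort
#'
#' Draws a latent walking-ability factor per patient; the informative
#' features are affine in the latent factor with relative measurement noise
#' `noise_rel`, the measured distance is affine in the latent factor with
#' multiplicative noise `1 + N(0, noise_rel)` truncated positive, and the
#' remaining features are correlated nuisance draws independent of the
#' latent factor. Missing cells and outliers are injected at the stated
#' rates. With `noise_rel = missing_rate = outlier_rate = 0` the distance
#' is an exact deterministic function of the informative features.
#'
#' Defaults emulate a cohort of 511 patients with 92 aggregated gait
#' features and a distance distribution centered at 137 m with 33 m spread.
#'
#' @param n_patients Number of rows.
#' @param n_features Number of feature columns.
#' @param n_informative Number of features driven by the latent factor.
#' @param noise_rel Relative noise SD, applied multiplicatively to the
#'   distance and to the latent signal inside each informative feature.
#' @param missing_rate Per-cell missingness probability, in [0, 0.5).
#' @param outlier_rate Per-cell outlier probability, in [0, 0.5).
#' @param dist_center,dist_spread Center and spread (meters) of the
#'   distance distribution.
#' @param seed Integer seed; same seed, same table.
#' @return A [as_feature_table()] with target column `distance_m`, carrying
#'   a `ground_truth` attribute (latent factor, informative feature names
#'   and generating weights) retrievable with [ground_truth()].
#' @export
#' @examples
#' ft <- simulate_gait_cohort(n_patients = 100, n_features = 10, seed = 1)
#' mean(ft$distance_m)
simulate_gait_cohort <- function(n_patients = 511L, n_features = 92L,
                                 n_informative = 5L, noise_rel = 0.05,
                                 missing_rate = 0.01, outlier_rate = 0.005,
                                 dist_center = 137, dist_spread = 33,
                                 seed = 1L) {
  if (n_patients < 1 || n_features < 1) {
    abort_config("`n_patients` and `n_features` must be positive")
  }
  if (n_informative < 1 || n_informative > n_features) {
    abort_config("`n_informative` must lie in [1, n_features]")
  }
  if (noise_rel < 0) abort_config("`noise_rel` must be non-negative")
  if (missing_rate < 0 || missing_rate >= 0.5 ||
      outlier_rate < 0 || outlier_rate >= 0.5) {
    abort_config("`missing_rate` and `outlier_rate` must lie in [0, 0.5)")
  }
  if (dist_center <= 0 || dist_spread < 0) {
    abort_config("`dist_center` must be positive and `dist_spread` non-negative")
  }

  withr::with_seed(as.integer(seed), {
    z <- rnorm(n_patients)

    tmpl <- informative_templates()
    tmpl <- tmpl[rep(seq_len(nrow(tmpl)), length.out = n_informative), ]
    if (n_informative > nrow(informative_templates())) {
      tmpl$name <- make.unique(tmpl$name, sep = " #")
    }
    # informative loadings: sign chosen so most track ability positively
    load_sign <- rep(c(1, 1, 1, -1), length.out = n_informative)
    X_inf <- vapply(seq_len(n_informative), function(j) {
      zn <- z + noise_rel * rnorm(n_patients)
      tmpl$center[j] + load_sign[j] * tmpl$scale[j] * zn
    }, numeric(n_patients))

    n_nuis <- n_features - n_informative
    X_nuis <- NULL
    nuis_names <- character(0)
    if (n_nuis > 0) {
      r <- min(5L, n_nuis)  # shared low-rank structure
      U <- matrix(rnorm(n_patients * r), n_patients, r)
      Lam <- matrix(runif(r * n_nuis, -0.6, 0.6), r, n_nuis)
      shared_sd <- sqrt(colSums(Lam^2))
      idio <- matrix(rnorm(n_patients * n_nuis), n_patients, n_nuis)
      centers <- runif(n_nuis, 5, 120)
      scales <- centers * runif(n_nuis, 0.05, 0.25)
      Znuis <- U %*% Lam + sweep(idio, 2, pmax(1e-8, sqrt(pmax(0, 1 - shared_sd^2))), "*")
      X_nuis <- sweep(sweep(Znuis, 2, scales, "*"), 2, centers, "+")
      nuis_names <- sprintf("Gait Param %02d (a.u.)", seq_len(n_nuis))
    }

    X <- cbind(X_inf, X_nuis)
    colnames(X) <- c(tmpl$name, nuis_names)

    distance <- (dist_center + dist_spread * z) *
      (1 + noise_rel * rnorm(n_patients))
    distance <- pmax(distance, 1)

    if (outlier_rate > 0) {
      hit <- matrix(runif(length(X)) < outlier_rate, nrow(X), ncol(X))
      if (any(hit)) {
        col_means <- colMeans(X)
        infl <- runif(sum(hit), 4, 8)
        dev <- X - rep(col_means, each = nrow(X))
        X[hit] <- rep(col_means, each = nrow(X))[hit] + dev[hit] * infl
      }
    }
    if (missing_rate > 0) {
      X[matrix(runif(length(X)) < missing_rate, nrow(X), ncol(X))] <- NA_real_
    }

    tbl <- as_tibble(as.data.frame(X, check.names = FALSE))
    tbl$patient_id <- sprintf("P%04d", seq_len(n_patients))
    tbl$distance_m <- distance
    ft <- as_feature_table(tbl, target = "distance_m", id = "patient_id")
    attr(ft, "ground_truth") <- list(
      latent = z,
      informative = colnames(X)[seq_len(n_informative)],
      loadings = load_sign * tmpl$scale,
      dist_center = dist_center, dist_spread = dist_spread,
      noise_rel = noise_rel, seed = as.integer(seed))
    ft
  })
}

#' @describeIn simulate_gait_cohort Retrieve the generator's ground truth
#'   (latent factor, informative feature names, loadings).
#' @param ft A simulated `feature_table`.
#' @export
ground_truth <- function(ft) attr(ft, "ground_truth")
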