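# The staged fractional factorial design benchmark. Instead of crossing the
# full configuration space (repeats x learning rates x widths x depths x
# algorithms), the benchmark fixes an epoch budget, then sweeps the learning
# rate per algorithm on a mid-size model, then grids the model shape per
# algorithm at its optimal learning rate, and finally compares the
# algorithms at their optimized configurations. Every training run gets a
# seed derived deterministically from the master seed and its coordinates
# (stage, algorithm, configuration, experiment), so any stage can be
# re-executed in isolation and reproduces its records exactly.

#' Benchmark plan
#'
#' Holds every tunable of the staged benchmark. Defaults follow the
#' reference protocol: 10 repeats, 1000 epochs, 50 learning rates spaced
#' exponentially over 1e-6..1e-1, spread and depth grids 1..6, all seven
#' algorithms, mid-size sweep shape (3, 3).
#'
#' @param n_exp Repeated seeded experiments per configuration.
#' @param n_epoch Training epochs for every run.
#' @param c_lr Number of learning-rate grid points.
#' @param lr_bounds Length-2 positive vector, low < high; the grid is
#'   log-equispaced and includes both endpoints.
#' @param spreads,depths Integer vectors for the shape grid.
#' @param algorithms Subset of [ffdb_algorithms()].
#' @param sweep_spread,sweep_depth Fixed mid-size shape used during the
#'   learning-rate sweep.
#' @param probe_lr Small learning rate (below every algorithm's default)
#'   used by the epoch-calibration stage.
#' @param batch_size,train_fraction,outlier_k Passed to training, the
#'   split, and preprocessing respectively.
#' @param ma_window Moving-average window for learning-rate selection.
#' @return An `ffdb_plan`.
#' @export
ffdb_plan <- function(n_exp = 10L, n_epoch = 1000L, c_lr = 50L,
                      lr_bounds = c(1e-6, 1e-1),
                      spreads = 1:6, depths = 1:6,
                      algorithms = ffdb_algorithms(),
                      sweep_spread = 3, sweep_depth = 3L,
                      probe_lr = 1e-5, batch_size = 32L,
                      train_fraction = 0.8, outlier_k = 4,
                      ma_window = 3L) {
  if (n_exp < 1) abort_config("`n_exp` must be at least 1")
  if (c_lr < 1) abort_config("`c_lr` must be at least 1")
  if (length(lr_bounds) != 2 || any(lr_bounds <= 0) ||
      lr_bounds[1] >= lr_bounds[2]) {
    abort_config("`lr_bounds` must be positive with low < high")
  }
  if (length(spreads) == 0 || length(depths) == 0) {
    abort_config("shape grids must be non-empty")
  }
  bad <- setdiff(algorithms, ffdb_algorithms())
  if (length(bad) > 0 || length(algorithms) == 0) {
    abort_config(sprintf("unknown algorithms: %s", paste(bad, collapse = ", ")))
  }
  structure(list(
    n_exp = as.integer(n_exp), n_epoch = as.integer(n_epoch),
    c_lr = as.integer(c_lr), lr_bounds = as.numeric(lr_bounds),
    spreads = as.numeric(spreads), depths = as.integer(depths),
    algorithms = algorithms,
    sweep_spread = sweep_spread, sweep_depth = as.integer(sweep_depth),
    probe_lr = probe_lr, batch_size = as.integer(batch_size),
    train_fraction = train_fraction, outlier_k = outlier_k,
    ma_window = as.integer(ma_window)),
    class = "ffdb_plan")
}

#' @describeIn ffdb_plan The log-equispaced learning-rate grid.
#' @param plan An `ffdb_plan`.
#' @export
lr_grid <- function(plan) {
  if (plan$c_lr == 1) return(plan$lr_bounds[1])
  10^seq(log10(plan$lr_bounds[1]), log10(plan$lr_bounds[2]),
         length.out = plan$c_lr)
}

#' Size of the full optimization space
#'
#' Product of the per-dimension counts: repeats, learning rates, spreads,
#' depths, algorithms — the number of training runs an exhaustive crossing
#' would need, which is what the staged benchmark avoids.
#'
#' @param n_exp,c_lr,c_spread,c_depth,c_alg Positive integer counts.
#' @return The total run count (numeric).
#' @export
#' @examples
#' estimate_space(10, 50, 6, 6, 7)  # 126000
estimate_space <- function(n_exp, c_lr, c_spread, c_depth, c_alg) {
  counts <- c(n_exp, c_lr, c_spread, c_depth, c_alg)
  if (any(counts < 1) || any(counts != round(counts))) {
    abort_config("all counts must be positive integers")
  }
  prod(counts)
}

#' @describeIn ffdb_plan Closed-form number of training runs the staged
#'   benchmark executes: calibration (one per algorithm) plus
#'   `n_exp * (c_lr * A + spreads * depths * A + A)`.
#' @export
plan_run_count <- function(plan) {
  a <- length(plan$algorithms)
  cal <- a
  sweep <- plan$n_exp * plan$c_lr * a
  grid <- plan$n_exp * length(plan$spreads) * length(plan$depths) * a
  cmp <- plan$n_exp * a
  c(calibration = cal, lr_sweep = sweep, shape_grid = grid,
    comparison = cmp, total = cal + sweep + grid + cmp)
}

#' @export
print.ffdb_plan <- function(x, ...) {
  rc <- plan_run_count(x)
  cat(sprintf(
    "<ffdb_plan> %d algorithms, %d LR points, %dx%d shapes, n_exp = %d, %d epochs (%d staged runs; full space %g)\n",
    length(x$algorithms), x$c_lr, length(x$spreads), length(x$depths),
    x$n_exp, x$n_epoch, rc[["total"]],
    estimate_space(x$n_exp, x$c_lr, length(x$spreads), length(x$depths),
                   length(x$algorithms))))
  invisible(x)
}

# ---- experiment batches ----------------------------------------------------

# Stage identifiers entering the per-run seed derivation.
STAGE_ID <- c(calibration = 1L, lr_sweep = 2L, shape_grid = 3L,
              comparison = 4L)

# Runs `n_exp` seeded experiments of one configuration: each experiment
# re-splits the data, refits preprocessing on its training rows, trains a
# freshly initialized network and evaluates the validation RMSE in meters.
run_experiment_batch <- function(ft, plan, spread, depth, algorithm, lr,
                                 master_seed, stage, alg_idx, cfg_idx,
                                 n_exp = plan$n_exp, n_epoch = plan$n_epoch,
                                 keep_models = FALSE) {
  shape <- dffnn_shape(n_features(ft), spread, depth)
  rmse <- rep(NA_real_, n_exp)
  preds <- vector("list", n_exp)
  models <- if (keep_models) vector("list", n_exp) else NULL
  for (e in seq_len(n_exp)) {
    seed <- derive_seed(master_seed, STAGE_ID[[stage]], alg_idx, cfg_idx, e)
    sp <- split_feature_table(ft, plan$train_fraction, seed = seed)
    prep <- fit_preprocess(sp$train, outlier_k = plan$outlier_k)
    tr <- apply_preprocess(prep, sp$train)
    va <- apply_preprocess(prep, sp$validation)
    cfg <- train_config(algorithm, lr, n_epoch = n_epoch,
                        batch_size = plan$batch_size, seed = seed)
    fit <- fit_dffnn(tr, shape, cfg)
    if (!fit$diverged) {
      p <- predict(fit, va)
      measured <- va[[target_name(va)]]
      if (all(is.finite(p))) {
        rmse[e] <- sqrt(mean((p - measured)^2))
        preds[[e]] <- tibble(experiment = e, patient_id = va$patient_id,
                             measured = measured, predicted = p)
      }
    }
    if (keep_models) models[[e]] <- fit
  }
  failed <- !is.finite(rmse)
  list(rmse = rmse[!failed], n_failed = sum(failed),
       predictions = bind_rows(preds), models = models,
       n_runs = n_exp)
}

# ---- stages ----------------------------------------------------------------

#' Epoch calibration stage
#'
#' Trains each algorithm once at a small probe learning rate and the
#' mid-size sweep shape to produce convergence evidence for the configured
#' epoch budget. The budget is not adapted: a non-plateaued algorithm is
#' flagged, not rejected, because the subsequent sweep tunes the learning
#' rate that the epoch count interacts with.
#'
#' @param ft A `feature_table`.
#' @param plan An [ffdb_plan()].
#' @param seed Master seed.
#' @return List: `n_epoch`, `records` (tibble with per-algorithm final
#'   loss and plateau flag), `loss_histories` (tibble algorithm/epoch/loss),
#'   `n_runs`.
#' @export
calibrate_epochs <- function(ft, plan, seed = 1L) {
  records <- vector("list", length(plan$algorithms))
  histories <- vector("list", length(plan$algorithms))
  for (ai in seq_along(plan$algorithms)) {
    alg <- plan$algorithms[ai]
    run_seed <- derive_seed(seed, STAGE_ID[["calibration"]], ai, 1L, 1L)
    sp <- split_feature_table(ft, plan$train_fraction, seed = run_seed)
    prep <- fit_preprocess(sp$train, outlier_k = plan$outlier_k)
    tr <- apply_preprocess(prep, sp$train)
    shape <- dffnn_shape(n_features(ft), plan$sweep_spread, plan$sweep_depth)
    cfg <- train_config(alg, plan$probe_lr, n_epoch = plan$n_epoch,
                        batch_size = plan$batch_size, seed = run_seed)
    fit <- fit_dffnn(tr, shape, cfg)
    lh <- fit$loss_history
    records[[ai]] <- tibble(
      algorithm = alg,
      final_loss = if (length(lh)) tail(lh, 1) else NA_real_,
      plateau = loss_plateaued(lh),
      diverged = fit$diverged)
    histories[[ai]] <- tibble(algorithm = alg, epoch = seq_along(lh),
                              loss = lh)
  }
  list(n_epoch = plan$n_epoch, records = bind_rows(records),
       loss_histories = bind_rows(histories),
       n_runs = length(plan$algorithms))
}

# Plateau criterion: relative training-loss improvement over the final 10%
# of epochs (at least 2 points) below 1%.
loss_plateaued <- function(loss) {
  n <- length(loss)
  if (n < 2 || anyNA(loss) || any(!is.finite(loss))) return(FALSE)
  start <- min(n - 1L, max(1L, ceiling(0.9 * n)))
  first <- loss[start]
  if (first <= 0) return(TRUE)
  (first - loss[n]) / first < 0.01
}

#' Learning-rate sweep stage
#'
#' For every algorithm and every point of the exponential learning-rate
#' grid, runs `n_exp` seeded experiments on the fixed mid-size shape and
#' records the relative error and its SD. Diverged runs are scored by the
#' failed-run policy and never abort the sweep. The optimal rate per
#' algorithm is the minimum of the moving-averaged curve
#' ([select_optimal_lr()]); an algorithm whose whole curve failed is
#' excluded with a warning.
#'
#' @inheritParams calibrate_epochs
#' @return List: `records` (algorithm, lr_index, lr, msearr, msearr_sd,
#'   n_exp, n_failed), `selection` (algorithm, lr), `n_runs`.
#' @export
lr_sweep <- function(ft, plan, seed = 1L) {
  grid <- lr_grid(plan)
  dist_avg <- mean(ft[[target_name(ft)]])
  records <- list()
  for (ai in seq_along(plan$algorithms)) {
    alg <- plan$algorithms[ai]
    for (li in seq_along(grid)) {
      batch <- run_experiment_batch(
        ft, plan, plan$sweep_spread, plan$sweep_depth, alg, grid[li],
        master_seed = seed, stage = "lr_sweep", alg_idx = ai, cfg_idx = li)
      q <- msearr(batch$rmse, dist_avg, batch$n_failed)
      records[[length(records) + 1L]] <- mutate(
        q, algorithm = alg, lr_index = li, lr = grid[li], .before = 1)
    }
  }
  records <- bind_rows(records)
  sel <- list()
  for (alg in plan$algorithms) {
    sub <- filter(records, .data$algorithm == alg)
    if (all(sub$n_exp == 0)) {
      warn(sprintf("algorithm %s failed at every learning rate; excluded", alg))
      next
    }
    sel[[length(sel) + 1L]] <- tibble(
      algorithm = alg,
      lr = select_optimal_lr(sub$lr, sub$msearr, window = plan$ma_window))
  }
  list(records = records, selection = bind_rows(sel),
       n_runs = plan$n_exp * plan$c_lr * length(plan$algorithms))
}

#' Select the optimal learning rate from a sweep curve
#'
#' Smooths the relative-error curve (ordered by increasing learning rate)
#' with a centered moving average and returns the learning rate at the
#' smoothed minimum; ties break toward the smaller rate. Smoothing guards
#' the selection against single-experiment noise spikes.
#'
#' @param lr Learning-rate grid (any order; sorted internally).
#' @param msearr Relative errors matching `lr`.
#' @param window Odd moving-average window (default 3).
#' @return The selected learning rate.
#' @export
select_optimal_lr <- function(lr, msearr, window = 3L) {
  if (length(lr) != length(msearr)) {
    abort_config("`lr` and `msearr` must have equal length")
  }
  if (length(lr) == 0) {
    abort_config("`lr` must not be empty")
  }
  ord <- order(lr)
  lr <- lr[ord]
  sm <- moving_average(msearr[ord], window = window)
  lr[which.min(sm)]  # which.min returns the first (smallest-lr) minimum
}

#' Model-shape grid stage
#'
#' Evaluates every spread x depth combination for one algorithm at its
#' optimal learning rate, `n_exp` experiments each, recording the relative
#' error and SD matrices. The best shape is the minimal-error cell; ties
#' break toward smaller spread, then smaller depth.
#'
#' @inheritParams calibrate_epochs
#' @param algorithm Algorithm name.
#' @param lr The algorithm's optimal learning rate.
#' @param alg_idx Index of the algorithm in `plan$algorithms` (seed
#'   coordinate; defaults to its position).
#' @return List: `records` (spread, depth, msearr, msearr_sd, n_exp,
#'   n_failed), `selection` (one-row tibble), `n_runs`.
#' @export
shape_grid <- function(ft, plan, algorithm, lr, seed = 1L,
                       alg_idx = match(algorithm, plan$algorithms)) {
  if (is.na(alg_idx)) abort_config("algorithm not in the plan")
  combos <- tidyr::expand_grid(spread = plan$spreads, depth = plan$depths)
  dist_avg <- mean(ft[[target_name(ft)]])
  records <- purrr::map_dfr(seq_len(nrow(combos)), function(ci) {
    batch <- run_experiment_batch(
      ft, plan, combos$spread[ci], combos$depth[ci], algorithm, lr,
      master_seed = seed, stage = "shape_grid", alg_idx = alg_idx,
      cfg_idx = ci)
    mutate(msearr(batch$rmse, dist_avg, batch$n_failed),
           spread = combos$spread[ci], depth = combos$depth[ci],
           .before = 1)
  })
  usable <- filter(records, .data$n_exp > 0)
  if (nrow(usable) == 0) abort_data(
    sprintf("every shape failed for algorithm %s", algorithm))
  best <- usable |>
    arrange(.data$msearr, .data$spread, .data$depth) |>
    slice(1)
  list(records = mutate(records, algorithm = algorithm, .before = 1),
       selection = tibble(algorithm = algorithm, spread = best$spread,
                          depth = best$depth, msearr = best$msearr),
       n_runs = plan$n_exp * nrow(combos))
}

#' Final algorithm comparison stage
#'
#' Runs `n_exp` fresh experiments per surviving algorithm at its optimized
#' configuration, keeps the trained models of every experiment (the
#' winner's become the reverse-weight ensemble), and declares the
#' algorithm with minimal relative error the winner; ties break toward the
#' plan's algorithm order.
#'
#' @inheritParams calibrate_epochs
#' @param best_configs Tibble with columns `algorithm`, `lr`, `spread`,
#'   `depth` — one optimized configuration per surviving algorithm.
#' @return List: `records`, `winner` (one-row tibble), `predictions`
#'   (winner's aggregated prediction pairs), `error_distribution`,
#'   `models` (winner's trained ensemble), `n_runs`.
#' @export
compare_algorithms <- function(ft, plan, best_configs, seed = 1L) {
  if (nrow(best_configs) == 0) abort_data("no surviving algorithms to compare")
  dist_avg <- mean(ft[[target_name(ft)]])
  out <- vector("list", nrow(best_configs))
  for (i in seq_len(nrow(best_configs))) {
    bc <- best_configs[i, ]
    ai <- match(bc$algorithm, plan$algorithms)
    batch <- run_experiment_batch(
      ft, plan, bc$spread, bc$depth, bc$algorithm, bc$lr,
      master_seed = seed, stage = "comparison", alg_idx = ai, cfg_idx = 1L,
      keep_models = TRUE)
    out[[i]] <- list(
      record = mutate(msearr(batch$rmse, dist_avg, batch$n_failed),
                      algorithm = bc$algorithm, lr = bc$lr,
                      spread = bc$spread, depth = bc$depth, .before = 1),
      batch = batch)
  }
  records <- bind_rows(purrr::map(out, "record"))
  # plan order is the deterministic tie-break
  ord <- order(records$msearr,
               match(records$algorithm, plan$algorithms))
  win_i <- ord[1]
  winner <- records[win_i, ]
  wbatch <- out[[win_i]]$batch
  ed <- if (nrow(wbatch$predictions) > 0) {
    error_distribution(wbatch$predictions$predicted,
                       wbatch$predictions$measured)
  } else NULL
  models <- purrr::discard(wbatch$models, ~ .x$diverged)
  list(records = records, winner = winner,
       predictions = wbatch$predictions, error_distribution = ed,
       models = models, n_runs = plan$n_exp * nrow(best_configs))
}

# ---- full benchmark --------------------------------------------------------

#' Run the staged benchmark end to end
#'
#' Executes epoch calibration, the learning-rate sweep, the shape grid for
#' every surviving algorithm, and the final comparison, assembling a
#' report that carries every stage's records and selections (the decision
#' path), the winning configuration, its error distribution, prediction
#' pairs and trained model ensemble, and the executed-run counter, which
#' always equals [plan_run_count()] for a full run. The report contains no
#' timestamps or other non-reproducible content: the same table, plan and
#' master seed yield an identical report.
#'
#' @inheritParams calibrate_epochs
#' @param through_stage Last stage to execute (default the full pipeline);
#'   earlier stages always run. Useful to inspect or export a partial
#'   benchmark.
#' @return An `ffdb_report`.
#' @export
run_ffdb <- function(ft, plan = ffdb_plan(), seed = 1L,
                     through_stage = c("comparison", "shape_grid",
                                       "lr_sweep", "calibration")) {
  through_stage <- match.arg(through_stage)
  stopifnot(inherits(plan, "ffdb_plan"))
  ft <- as_feature_table(ft, target = target_name(ft))
  if (anyNA(ft[[target_name(ft)]])) {
    abort_data("the benchmark requires a measured distance for every patient")
  }
  want <- match(through_stage,
                c("calibration", "lr_sweep", "shape_grid", "comparison"))
  dist_avg <- mean(ft[[target_name(ft)]])
  n_runs <- 0L

  calibration <- calibrate_epochs(ft, plan, seed = seed)
  n_runs <- n_runs + calibration$n_runs
  sweep <- optimal_lr <- grids <- best_shapes <- comparison <- NULL

  if (want >= 2) {
    sweep <- lr_sweep(ft, plan, seed = seed)
    n_runs <- n_runs + sweep$n_runs
    optimal_lr <- sweep$selection
  }
  if (want >= 3) {
    grids <- purrr::map(seq_len(nrow(optimal_lr)), function(i) {
      shape_grid(ft, plan, optimal_lr$algorithm[i], optimal_lr$lr[i],
                 seed = seed)
    })
    n_runs <- n_runs + sum(purrr::map_int(grids, "n_runs"))
    best_shapes <- bind_rows(purrr::map(grids, "selection"))
  }
  if (want >= 4) {
    best_configs <- left_join(optimal_lr,
                              select(best_shapes, "algorithm", "spread",
                                     "depth"),
                              by = "algorithm")
    comparison <- compare_algorithms(ft, plan, best_configs, seed = seed)
    n_runs <- n_runs + comparison$n_runs
  }

  best_config <- NULL
  if (!is.null(comparison)) {
    w <- comparison$winner
    best_config <- list(algorithm = w$algorithm, learning_rate = w$lr,
                        spread = w$spread, depth = w$depth,
                        n_epoch = plan$n_epoch, msearr = w$msearr,
                        msearr_sd = w$msearr_sd)
  }
  structure(list(
    plan = plan, master_seed = as.integer(seed),
    n_patients = nrow(ft), n_features = n_features(ft),
    dist_avg = dist_avg,
    calibration = calibration,
    lr_sweep = sweep,
    shape_grid = if (!is.null(grids))
      list(records = bind_rows(purrr::map(grids, "records")),
           selection = best_shapes) else NULL,
    comparison = if (!is.null(comparison))
      list(records = comparison$records, winner = comparison$winner) else NULL,
    best_config = best_config,
    error_distribution = comparison$error_distribution,
    predictions = comparison$predictions,
    winner_models = comparison$models,
    run_count = n_runs,
    decision_path = list(
      n_epoch = plan$n_epoch,
      optimal_lr = optimal_lr,
      best_shapes = best_shapes,
      winner = if (!is.null(comparison)) comparison$winner else NULL)),
    class = "ffdb_report")
}

#' @describeIn run_ffdb Per-algorithm comparison records (falls back to the
#'   deepest stage that ran).
#' @param x An `ffdb_report`.
#' @param ... Unused.
#' @export
tidy.ffdb_report <- function(x, ...) {
  if (!is.null(x$comparison)) return(x$comparison$records)
  if (!is.null(x$shape_grid)) return(x$shape_grid$records)
  if (!is.null(x$lr_sweep)) return(x$lr_sweep$records)
  x$calibration$records
}

#' @describeIn run_ffdb One-row benchmark summary.
#' @export
glance.ffdb_report <- function(x, ...) {
  bc <- x$best_config
  tibble(
    n_patients = x$n_patients, n_features = x$n_features,
    dist_avg = x$dist_avg, run_count = x$run_count,
    algorithm = bc$algorithm %||% NA_character_,
    learning_rate = bc$learning_rate %||% NA_real_,
    spread = bc$spread %||% NA_real_, depth = bc$depth %||% NA_integer_,
    msearr = bc$msearr %||% NA_real_, msearr_sd = bc$msearr_sd %||% NA_real_)
}

#' @export
print.ffdb_report <- function(x, ...) {
  cat(sprintf("<ffdb_report> %d patients x %d features, %d runs\n",
              x$n_patients, x$n_features, x$run_count))
  if (!is.null(x$best_config)) {
    bc <- x$best_config
    cat(sprintf("  best: %s, LR = %.6g, shape (%g, %d), MSEarr = %.4f\n",
                bc$algorithm, bc$learning_rate, bc$spread, bc$depth,
                bc$msearr))
  } else {
    cat("  (partial benchmark)\n")
  }
  invisible(x)
}
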