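# Machine-readable benchmark artifacts. All floating-point values are
# written as 17-significant-digit decimal strings, which reproduce IEEE
# doubles exactly, so a write/read cycle is the identity on the report's
# numeric content. Structured selections live in report.json (numbers as
# full-precision strings); per-configuration records and prediction pairs
# are CSV so they feed external plotting directly.

num_out <- function(x) format_full(as.numeric(x))
num_in <- function(x) {
  if (is.null(x)) return(NA_real_)
  as.numeric(x)
}

write_stage_csv <- function(tbl, path) {
  out <- as.data.frame(tbl)
  for (col in names(out)) {
    if (is.double(out[[col]])) {
      v <- format_full(out[[col]])
      # keep a decimal marker so the reader can distinguish doubles that
      # happen to be whole numbers from true integer columns
      whole <- !is.na(v) & grepl("^-?[0-9]+$", v)
      v[whole] <- paste0(v[whole], ".0")
      out[[col]] <- v
    }
  }
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE, na = "")
}

read_stage_csv <- function(path, char_cols = character(0)) {
  # everything is read as character and converted with base R's strtod,
  # which (unlike fast CSV float parsers) is correctly rounded — required
  # for the bit-identical round-trip contract
  raw <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                         na = "", progress = FALSE, show_col_types = FALSE)
  for (col in setdiff(names(raw), char_cols)) {
    v <- raw[[col]]
    obs <- v[!is.na(v)]
    if (length(obs) > 0 && all(obs %in% c("TRUE", "FALSE"))) {
      raw[[col]] <- as.logical(v)
    } else if (length(obs) > 0 && all(grepl("^-?[0-9]{1,9}$", obs))) {
      raw[[col]] <- as.integer(v)
    } else {
      conv <- suppressWarnings(as.numeric(v))
      if (!any(is.na(conv) & !is.na(v))) raw[[col]] <- conv
    }
  }
  as_tibble(raw)
}

#' Export a benchmark report to a directory
#'
#' Writes `report.json` (plan, selections, best configuration, counters)
#' plus one CSV per available stage (calibration records and loss
#' histories, learning-rate curves, shape grids, final comparison, the
#' winner's per-run prediction pairs). A partial report — one produced with
#' `through_stage` before the comparison — is flagged as such in
#' `report.json` and exports only its finished stages. Reading the
#' directory back with [read_ffdb_report()] reproduces every exported
#' number bit-identically.
#'
#' @param report An `ffdb_report`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_ffdb_report <- function(report, dir) {
  stopifnot(inherits(report, "ffdb_report"))
  stages_present <- c(
    calibration = !is.null(report$calibration),
    lr_sweep = !is.null(report$lr_sweep),
    shape_grid = !is.null(report$shape_grid),
    comparison = !is.null(report$comparison))
  if (!any(stages_present)) {
    abort_config("report contains no finished stage; nothing to export")
  }
  ok <- dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(dir)) abort_io(sprintf("cannot create directory %s", dir))

  plan <- report$plan
  meta <- list(
    format = "ffdb_report/1",
    partial = !stages_present[["comparison"]],
    stages_present = as.list(stages_present),
    master_seed = report$master_seed,
    n_patients = report$n_patients,
    n_features = report$n_features,
    run_count = report$run_count,
    dist_avg = num_out(report$dist_avg),
    plan = list(
      n_exp = plan$n_exp, n_epoch = plan$n_epoch, c_lr = plan$c_lr,
      lr_bounds = num_out(plan$lr_bounds),
      spreads = num_out(plan$spreads), depths = plan$depths,
      algorithms = plan$algorithms,
      sweep_spread = num_out(plan$sweep_spread),
      sweep_depth = plan$sweep_depth,
      probe_lr = num_out(plan$probe_lr), batch_size = plan$batch_size,
      train_fraction = num_out(plan$train_fraction),
      outlier_k = num_out(plan$outlier_k), ma_window = plan$ma_window))
  if (!is.null(report$best_config)) {
    bc <- report$best_config
    meta$best_config <- list(
      algorithm = bc$algorithm, learning_rate = num_out(bc$learning_rate),
      spread = num_out(bc$spread), depth = bc$depth,
      n_epoch = bc$n_epoch, msearr = num_out(bc$msearr),
      msearr_sd = num_out(bc$msearr_sd))
  }
  if (!is.null(report$error_distribution)) {
    meta$error_fractions <- as.list(
      num_out(report$error_distribution$fractions))
    names(meta$error_fractions) <- names(report$error_distribution$fractions)
  }
  jsonlite::write_json(meta, file.path(dir, "report.json"),
                       auto_unbox = TRUE, pretty = TRUE)

  if (stages_present[["calibration"]]) {
    write_stage_csv(report$calibration$records,
                    file.path(dir, "calibration.csv"))
    write_stage_csv(report$calibration$loss_histories,
                    file.path(dir, "calibration_loss.csv"))
  }
  if (stages_present[["lr_sweep"]]) {
    write_stage_csv(report$lr_sweep$records, file.path(dir, "lr_sweep.csv"))
    write_stage_csv(report$lr_sweep$selection,
                    file.path(dir, "optimal_lr.csv"))
  }
  if (stages_present[["shape_grid"]]) {
    write_stage_csv(report$shape_grid$records,
                    file.path(dir, "shape_grid.csv"))
    write_stage_csv(report$shape_grid$selection,
                    file.path(dir, "best_shapes.csv"))
  }
  if (stages_present[["comparison"]]) {
    write_stage_csv(report$comparison$records,
                    file.path(dir, "comparison.csv"))
    if (!is.null(report$predictions) && nrow(report$predictions) > 0) {
      write_stage_csv(report$predictions, file.path(dir, "predictions.csv"))
    }
    if (!is.null(report$error_distribution)) {
      write_stage_csv(report$error_distribution$histogram,
                      file.path(dir, "error_histogram.csv"))
    }
  }
  invisible(dir)
}

#' Read a benchmark report back from a directory
#'
#' Inverse of [write_ffdb_report()] for everything exported (trained model
#' ensembles are not serialized; the winner's error distribution is
#' recomputed from the exported prediction pairs and reproduces the
#' original exactly).
#'
#' @param dir Directory written by [write_ffdb_report()].
#' @return An `ffdb_report`.
#' @export
read_ffdb_report <- function(dir) {
  jpath <- file.path(dir, "report.json")
  if (!file.exists(jpath)) abort_io(sprintf("no report.json under %s", dir))
  meta <- jsonlite::read_json(jpath, simplifyVector = TRUE)
  p <- meta$plan
  plan <- ffdb_plan(
    n_exp = p$n_exp, n_epoch = p$n_epoch, c_lr = p$c_lr,
    lr_bounds = num_in(p$lr_bounds), spreads = num_in(p$spreads),
    depths = p$depths, algorithms = p$algorithms,
    sweep_spread = num_in(p$sweep_spread), sweep_depth = p$sweep_depth,
    probe_lr = num_in(p$probe_lr), batch_size = p$batch_size,
    train_fraction = num_in(p$train_fraction),
    outlier_k = num_in(p$outlier_k), ma_window = p$ma_window)

  present <- meta$stages_present
  calibration <- lr_sweep <- shape_grid <- comparison <- NULL
  predictions <- error_distribution <- best_config <- NULL
  if (isTRUE(present$calibration)) {
    calibration <- list(
      n_epoch = plan$n_epoch,
      records = read_stage_csv(file.path(dir, "calibration.csv"),
                               char_cols = "algorithm"),
      loss_histories = read_stage_csv(file.path(dir, "calibration_loss.csv"),
                                      char_cols = "algorithm"),
      n_runs = length(plan$algorithms))
  }
  if (isTRUE(present$lr_sweep)) {
    lr_sweep <- list(
      records = read_stage_csv(file.path(dir, "lr_sweep.csv"),
                               char_cols = "algorithm"),
      selection = read_stage_csv(file.path(dir, "optimal_lr.csv"),
                                 char_cols = "algorithm"),
      n_runs = plan$n_exp * plan$c_lr * length(plan$algorithms))
  }
  if (isTRUE(present$shape_grid)) {
    shape_grid <- list(
      records = read_stage_csv(file.path(dir, "shape_grid.csv"),
                               char_cols = "algorithm"),
      selection = read_stage_csv(file.path(dir, "best_shapes.csv"),
                                 char_cols = "algorithm"))
  }
  if (isTRUE(present$comparison)) {
    records <- read_stage_csv(file.path(dir, "comparison.csv"),
                              char_cols = "algorithm")
    ppath <- file.path(dir, "predictions.csv")
    if (file.exists(ppath)) {
      predictions <- read_stage_csv(ppath, char_cols = "patient_id")
      error_distribution <- error_distribution(predictions$predicted,
                                               predictions$measured)
    }
    bc <- meta$best_config
    best_config <- list(
      algorithm = bc$algorithm, learning_rate = num_in(bc$learning_rate),
      spread = num_in(bc$spread), depth = bc$depth, n_epoch = bc$n_epoch,
      msearr = num_in(bc$msearr), msearr_sd = num_in(bc$msearr_sd))
    win <- filter(records, .data$algorithm == bc$algorithm)
    comparison <- list(records = records, winner = win)
  }
  structure(list(
    plan = plan, master_seed = meta$master_seed,
    n_patients = meta$n_patients, n_features = meta$n_features,
    dist_avg = num_in(meta$dist_avg),
    calibration = calibration, lr_sweep = lr_sweep,
    shape_grid = shape_grid, comparison = comparison,
    best_config = best_config, error_distribution = error_distribution,
    predictions = predictions, winner_models = NULL,
    run_count = meta$run_count,
    decision_path = list(
      n_epoch = plan$n_epoch,
      optimal_lr = if (!is.null(lr_sweep)) lr_sweep$selection else NULL,
      best_shapes = if (!is.null(shape_grid)) shape_grid$selection else NULL,
      winner = if (!is.null(comparison)) comparison$winner else NULL)),
    class = "ffdb_report")
}
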