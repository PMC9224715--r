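# Single configuration access point: one YAML (or JSON) file describes the
# data source, the benchmark plan, the master seed and the output
# directory, so an entire benchmark — and any re-run of it — is specified
# by one document. Unknown keys are rejected outright: a typo must fail
# fast, not silently fall back to a default.

check_keys <- function(x, allowed, where) {
  extra <- setdiff(names(x), allowed)
  if (length(extra) > 0) {
    abort_config(sprintf("unknown key(s) in %s: %s", where,
                         paste(extra, collapse = ", ")))
  }
}

#' Read a benchmark run configuration
#'
#' YAML by default; files ending in `.json` are parsed as JSON. The
#' document has three sections: `data` (either `path` + `target` for a CSV
#' table, or `synthetic` holding [simulate_gait_cohort()] arguments),
#' `plan` ([ffdb_plan()] arguments), and the scalars `seed` and `output`.
#' Unknown keys anywhere are configuration errors.
#'
#' @param path Path to the configuration file.
#' @return A validated `ffdb_config` list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) abort_io(sprintf("config file not found: %s", path))
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  validate_run_config(cfg)
}

#' @describeIn read_run_config Validate an in-memory configuration list.
#' @param cfg A named list.
#' @export
validate_run_config <- function(cfg) {
  check_keys(cfg, c("data", "plan", "seed", "output"), "config")
  if (is.null(cfg$data)) abort_config("config needs a `data` section")
  check_keys(cfg$data, c("path", "target", "id", "synthetic"), "data")
  has_path <- !is.null(cfg$data$path)
  has_syn <- !is.null(cfg$data$synthetic)
  if (has_path == has_syn) {
    abort_config("`data` needs exactly one of `path` or `synthetic`")
  }
  if (has_path && is.null(cfg$data$target)) {
    abort_config("`data.target` is required with `data.path`")
  }
  if (has_syn) {
    check_keys(cfg$data$synthetic,
               names(formals(simulate_gait_cohort)), "data.synthetic")
  }
  if (!is.null(cfg$plan)) {
    check_keys(cfg$plan, names(formals(ffdb_plan)), "plan")
  }
  cfg$seed <- as.integer(cfg$seed %||% 1L)
  structure(cfg, class = "ffdb_config")
}

#' @describeIn read_run_config Write a configuration back to YAML (the
#'   round trip is lossless).
#' @param file Output path.
#' @export
write_run_config <- function(cfg, file) {
  yaml::write_yaml(unclass(cfg), file)
  invisible(file)
}

# Materialize the configured data source.
config_data <- function(cfg) {
  if (!is.null(cfg$data$synthetic)) {
    do.call(simulate_gait_cohort, cfg$data$synthetic)
  } else {
    read_feature_table(cfg$data$path, target = cfg$data$target,
                       id = cfg$data$id)
  }
}

#' Run a benchmark from a configuration
#'
#' Loads (or simulates) the configured feature table, builds the plan,
#' runs [run_ffdb()] under the configured master seed, embeds the full
#' configuration in the report (so the report regenerates from itself),
#' and, when `output` is set, exports the report with
#' [write_ffdb_report()].
#'
#' @param cfg An `ffdb_config`, or a path to one.
#' @param through_stage Passed to [run_ffdb()].
#' @return The `ffdb_report`, with the configuration attached as `$config`.
#' @export
run_benchmark_config <- function(cfg, through_stage = "comparison") {
  if (is.character(cfg)) cfg <- read_run_config(cfg)
  cfg <- validate_run_config(cfg)
  ft <- config_data(cfg)
  plan <- do.call(ffdb_plan, cfg$plan %||% list())
  report <- run_ffdb(ft, plan, seed = cfg$seed,
                     through_stage = through_stage)
  report$config <- cfg
  if (!is.null(cfg$output)) {
    write_ffdb_report(report, cfg$output)
    write_run_config(cfg, file.path(cfg$output, "run_config.yaml"))
  }
  report
}
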