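# ggplot2 views of the benchmark artifacts, mirroring the analysis
# strategy: line charts (raw and moving-averaged) for the learning-rate
# dependency per algorithm, heat maps for the shape grids, bars for the
# final comparison, and histogram/scatter for the winner's predictions.

#' Learning-rate sweep curves
#'
#' @param report An `ffdb_report` with a finished sweep stage.
#' @param smooth Overlay the moving-averaged curve used for selection.
#' @return A ggplot.
#' @export
plot_lr_sweep <- function(report, smooth = TRUE) {
  if (is.null(report$lr_sweep)) abort_config("report has no sweep stage")
  rec <- report$lr_sweep$records |>
    group_by(.data$algorithm) |>
    arrange(.data$lr, .by_group = TRUE) |>
    mutate(msearr_smooth = moving_average(.data$msearr,
                                          report$plan$ma_window)) |>
    ungroup()
  p <- ggplot2::ggplot(rec, ggplot2::aes(x = .data$lr, y = .data$msearr)) +
    ggplot2::geom_line(alpha = if (smooth) 0.35 else 1) +
    ggplot2::facet_wrap(~algorithm) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "learning rate", y = "MSEarr (relative error)") +
    ggplot2::theme_minimal()
  if (smooth) {
    p <- p + ggplot2::geom_line(ggplot2::aes(y = .data$msearr_smooth))
  }
  p
}

#' Shape-grid heat map
#'
#' @param report An `ffdb_report` with a finished shape-grid stage.
#' @param value Which matrix to show: relative error or its SD.
#' @return A ggplot.
#' @export
plot_shape_grid <- function(report, value = c("msearr", "msearr_sd")) {
  if (is.null(report$shape_grid)) abort_config("report has no shape-grid stage")
  value <- match.arg(value)
  ggplot2::ggplot(report$shape_grid$records,
                  ggplot2::aes(x = factor(.data$spread),
                               y = factor(.data$depth),
                               fill = .data[[value]])) +
    ggplot2::geom_tile() +
    ggplot2::facet_wrap(~algorithm) +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = "model spread", y = "model depth", fill = value) +
    ggplot2::theme_minimal()
}

#' Final algorithm comparison bars
#'
#' @param report An `ffdb_report` with a finished comparison stage.
#' @return A ggplot.
#' @export
plot_algorithm_comparison <- function(report) {
  if (is.null(report$comparison)) abort_config("report has no comparison stage")
  rec <- report$comparison$records
  ggplot2::ggplot(rec, ggplot2::aes(x = stats::reorder(.data$algorithm,
                                                       .data$msearr),
                                    y = .data$msearr)) +
    ggplot2::geom_col() +
    ggplot2::geom_errorbar(ggplot2::aes(
      ymin = .data$msearr - .data$msearr_sd,
      ymax = .data$msearr + .data$msearr_sd), width = 0.25, na.rm = TRUE) +
    ggplot2::labs(x = NULL, y = "MSEarr (relative error)") +
    ggplot2::theme_minimal()
}

#' @describeIn error_distribution Histogram and measured-vs-predicted
#'   scatter of the winner's aggregated validation predictions.
#' @param object An `error_distribution`.
#' @param type `"histogram"` or `"scatter"`.
#' @param ... Unused.
#' @export
autoplot.error_distribution <- function(object,
                                        type = c("histogram", "scatter"),
                                        ...) {
  type <- match.arg(type)
  if (type == "histogram") {
    ggplot2::ggplot(object$histogram,
                    ggplot2::aes(x = .data$mid, y = .data$count)) +
      ggplot2::geom_col(width = 4.5) +
      ggplot2::labs(x = "signed prediction error (m)", y = "count") +
      ggplot2::theme_minimal()
  } else {
    ggplot2::ggplot(object$scatter,
                    ggplot2::aes(x = .data$measured, y = .data$predicted)) +
      ggplot2::geom_point(alpha = 0.4) +
      ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2) +
      ggplot2::labs(x = "measured distance (m)",
                    y = "predicted distance (m)") +
      ggplot2::theme_minimal()
  }
}

#' @describeIn run_ffdb Dispatch to the stage plots.
#' @param object An `ffdb_report`.
#' @param type One of `"lr_sweep"`, `"shape_grid"`, `"comparison"`,
#'   `"errors"`.
#' @export
autoplot.ffdb_report <- function(object,
                                 type = c("comparison", "lr_sweep",
                                          "shape_grid", "errors"), ...) {
  type <- match.arg(type)
  switch(type,
         lr_sweep = plot_lr_sweep(object),
         shape_grid = plot_shape_grid(object),
         comparison = plot_algorithm_comparison(object),
         errors = autoplot(object$error_distribution))
}

#' @describeIn train_dffnn Training-loss curve.
#' @param object A trained `dffnn`.
#' @export
autoplot.dffnn <- function(object, ...) {
  ggplot2::ggplot(tidy(object), ggplot2::aes(x = .data$epoch,
                                             y = .data$loss)) +
    ggplot2::geom_line() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "epoch", y = "training MSE (m²)") +
    ggplot2::theme_minimal()
}
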