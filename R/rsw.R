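# Reverse synapse weights: a white-box feature-impact score obtained by
# propagating weight mass backwards from the output neuron. The output
# neuron carries reverse weight 1; each earlier neuron receives the
# width-averaged, sign-preserving weighted sum of its successors' reverse
# weights. Activations and biases play no role — the score reflects the
# synapse weights alone, which is what makes it a cheap structural sanity
# check rather than a gradient attribution.

#' Reverse synapse weights of the input features
#'
#' Backward recursion over the layer weights: `rw(output) = 1` and, for a
#' layer mapping width-`p` neurons to width-`q` neurons through matrix `W`
#' (row = source, column = destination), `rw_source = (W %*% rw_dest) / q`.
#' Signs are retained and the result is not normalized. Equivalent to
#' summing, over all input-to-output paths, the product of path weights
#' scaled by the product of the traversed layer widths' reciprocals.
#'
#' @param model A `dffnn` (trained or untrained).
#' @return Numeric vector of per-input reverse weights, named with the
#'   model's feature names when known.
#' @export
#' @examples
#' m <- build_dffnn(dffnn_shape(4, spread = 1, depth = 2), seed = 1)
#' reverse_weights(m)
reverse_weights <- function(model) {
  stopifnot(inherits(model, "dffnn"))
  layers <- model$layers
  if (length(layers) == 0) abort_data("model has no layers")
  rw <- 1
  for (l in rev(seq_along(layers))) {
    W <- layers[[l]]$W
    if (ncol(W) != length(rw)) abort_data("inconsistent layer weight shapes")
    rw <- as.numeric(W %*% rw) / ncol(W)
  }
  if (!is.null(model$feature_names)) names(rw) <- model$feature_names
  rw
}

#' Ensemble-averaged reverse-weight table
#'
#' Per-feature mean of [reverse_weights()] across an ensemble of models
#' sharing the input layout (typically the repeated experiments of the
#' benchmark's best configuration), ranked by descending reverse weight.
#'
#' @param models List of `dffnn` models with identical input dimension.
#' @param feature_names Optional character vector of feature names;
#'   defaults to the first model's.
#' @return Tibble with `feature`, `reverse_weight`, `rank` (1 = largest).
#' @export
rsw_table <- function(models, feature_names = NULL) {
  if (length(models) == 0) abort_data("empty model ensemble")
  dims <- unique(purrr::map_int(models, ~ .x$shape$input_dim))
  if (length(dims) != 1) abort_config("models have differing input dimensions")
  feature_names <- feature_names %||% models[[1]]$feature_names %||%
    paste0("feature_", seq_len(dims))
  if (length(feature_names) != dims) {
    abort_config("feature_names length does not match the input dimension")
  }
  rw <- rowMeans(vapply(models, reverse_weights, numeric(dims)))
  tibble(feature = feature_names, reverse_weight = rw) |>
    arrange(desc(.data$reverse_weight)) |>
    mutate(rank = row_number())
}

#' Top and bottom impact features
#'
#' The `k` largest and `k` smallest reverse weights, in rank order — the
#' benchmark's sanity-check excerpt: the high-impact end should read like
#' cadence/speed/stride, the low end like redundant or counteracting
#' features.
#'
#' @param table A [rsw_table()] result.
#' @param k Excerpt size per end (default 5).
#' @return Tibble with `group` ("top"/"bottom"), `feature`,
#'   `reverse_weight`, `rank`.
#' @export
top_bottom_features <- function(table, k = 5L) {
  if (nrow(table) < 2 * k) {
    abort_config(sprintf("need at least %d features for k = %d", 2 * k, k))
  }
  ordered <- arrange(table, .data$rank)
  bind_rows(
    mutate(head(ordered, k), group = "top"),
    mutate(tail(ordered, k), group = "bottom")) |>
    select("group", "feature", "reverse_weight", "rank")
}
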