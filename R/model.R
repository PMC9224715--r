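# Deep feed-forward regressor of parameterized shape: `spread` scales every
# hidden layer's width relative to the input dimension, `depth` counts the
# hidden layers, the output is a single linear neuron (predicted distance in
# meters). Hidden activation is ReLU; loss is mean squared error. Training
# runs in compiled code (src/dffnn.cpp) under one of seven first-order
# algorithms whose secondary hyperparameters stay at their conventional
# defaults — only the learning rate is tuned.

#' Model shape descriptor
#'
#' Every hidden layer has width `round(spread * input_dim)` (at least 1);
#' there are `depth` hidden layers and a single linear output neuron.
#'
#' @param input_dim Number of input features.
#' @param spread Positive hidden-width factor relative to `input_dim`.
#' @param depth Positive integer number of hidden layers.
#' @return A `dffnn_shape` list with `input_dim`, `spread`, `depth`, `width`.
#' @export
#' @examples
#' dffnn_shape(92, spread = 5, depth = 6)$width  # 460
dffnn_shape <- function(input_dim, spread, depth) {
  if (input_dim < 1) abort_config("`input_dim` must be a positive integer")
  if (!is.numeric(spread) || spread <= 0) abort_config("`spread` must be positive")
  if (depth < 1 || depth != round(depth)) {
    abort_config("`depth` must be a positive integer")
  }
  width <- as.integer(round_half_away(spread * input_dim))
  if (width < 1) {
    abort_config(sprintf("round(spread * input_dim) = %d is below 1", width))
  }
  structure(list(input_dim = as.integer(input_dim), spread = spread,
                 depth = as.integer(depth), width = width),
            class = "dffnn_shape")
}

#' Training configuration
#'
#' @param algorithm One of [ffdb_algorithms()].
#' @param learning_rate Positive learning rate.
#' @param n_epoch Positive integer number of training epochs.
#' @param batch_size Minibatch size (default 32).
#' @param seed Integer seed controlling weight initialization and shuffling.
#' @return A `train_config` list.
#' @export
train_config <- function(algorithm, learning_rate, n_epoch = 1000L,
                         batch_size = 32L, seed = 1L) {
  if (!algorithm %in% ffdb_algorithms()) {
    abort_config(sprintf(
      "unknown algorithm '%s'; must be one of %s", algorithm,
      paste(ffdb_algorithms(), collapse = ", ")))
  }
  if (!is.numeric(learning_rate) || learning_rate < 0) {
    abort_config("`learning_rate` must be non-negative")
  }
  if (n_epoch < 1) abort_config("`n_epoch` must be positive")
  if (batch_size < 1) abort_config("`batch_size` must be positive")
  structure(list(algorithm = algorithm, learning_rate = learning_rate,
                 n_epoch = as.integer(n_epoch),
                 batch_size = as.integer(batch_size),
                 seed = as.integer(seed)),
            class = "train_config")
}

#' Build an untrained network
#'
#' Glorot-uniform weights (zero biases), reproducible from `seed`
#' independently of R's global RNG state. The weight convention — used by
#' every consumer, including [reverse_weights()] — is a list of layers from
#' input to output, each with matrix `W` (row = source neuron, column =
#' destination neuron) and bias vector `b`.
#'
#' @param shape A [dffnn_shape()].
#' @param seed Integer seed.
#' @return An untrained `dffnn` object.
#' @export
build_dffnn <- function(shape, seed = 1L) {
  stopifnot(inherits(shape, "dffnn_shape"))
  init <- cpp_init_dffnn(shape$input_dim, shape$width, shape$depth,
                         as.integer(seed))
  layers <- purrr::map2(init$weights, init$biases,
                        function(W, b) list(W = W, b = as.numeric(b)))
  structure(list(shape = shape, layers = layers, trained = FALSE,
                 loss_history = numeric(0), diverged = FALSE,
                 config = NULL, seed = as.integer(seed),
                 feature_names = NULL),
            class = "dffnn")
}

#' Train a network on a preprocessed feature table
#'
#' Minimizes mean squared error between the predicted and measured distance
#' over `config$n_epoch` epochs of seeded minibatch updates. A run whose
#' loss becomes non-finite is not an error: it returns with `diverged =
#' TRUE` and is scored by the benchmark's failed-run policy.
#'
#' @param model An untrained `dffnn` from [build_dffnn()].
#' @param data A preprocessed `feature_table` (see [apply_preprocess()]);
#'   the target is in meters.
#' @param config A [train_config()].
#' @return The trained `dffnn` with per-epoch loss history.
#' @export
train_dffnn <- function(model, data, config) {
  stopifnot(inherits(model, "dffnn"), inherits(config, "train_config"))
  X <- feature_matrix(data)
  if (ncol(X) != model$shape$input_dim) {
    abort_config(sprintf(
      "data has %d features but the model expects %d",
      ncol(X), model$shape$input_dim))
  }
  y <- data[[target_name(data)]]
  if (anyNA(y)) abort_data("training target contains missing values")
  res <- cpp_train_dffnn(
    X, y,
    purrr::map(model$layers, "W"), purrr::map(model$layers, "b"),
    config$algorithm, config$learning_rate, config$n_epoch,
    config$batch_size, config$seed)
  lh <- res$loss_history
  lh <- lh[seq_len(max(which(!is.na(lh)), 0L))]
  model$layers <- purrr::map2(res$weights, res$biases,
                              function(W, b) list(W = W, b = as.numeric(b)))
  model$trained <- TRUE
  model$loss_history <- lh
  model$diverged <- res$diverged
  model$config <- config
  model$feature_names <- feature_names(data)
  model
}

#' Convenience wrapper: build and train in one call
#'
#' @inheritParams train_dffnn
#' @param shape A [dffnn_shape()].
#' @export
fit_dffnn <- function(data, shape, config) {
  train_dffnn(build_dffnn(shape, seed = config$seed), data, config)
}

#' Predict walking distances
#'
#' Pure forward pass through the stored weights (ReLU hidden layers, linear
#' output); one scalar in meters per row.
#'
#' @param object A `dffnn`.
#' @param newdata A `feature_table` (preprocessed like the training data) or
#'   a numeric matrix with `input_dim` columns.
#' @param ... Unused.
#' @return Numeric vector of predicted distances (meters).
#' @export
predict.dffnn <- function(object, newdata, ...) {
  X <- if (is.matrix(newdata)) newdata else feature_matrix(newdata)
  if (ncol(X) != object$shape$input_dim) {
    abort_config(sprintf(
      "newdata has %d features but the model expects %d",
      ncol(X), object$shape$input_dim))
  }
  A <- X
  L <- length(object$layers)
  for (l in seq_len(L)) {
    Z <- A %*% object$layers[[l]]$W
    Z <- sweep(Z, 2, object$layers[[l]]$b, "+")
    A <- if (l < L) pmax(Z, 0) else Z
  }
  as.numeric(A[, 1])
}

#' @describeIn train_dffnn Per-epoch training loss as a tibble.
#' @param x A `dffnn`.
#' @param ... Unused.
#' @export
tidy.dffnn <- function(x, ...) {
  tibble(epoch = seq_along(x$loss_history), loss = x$loss_history)
}

#' @describeIn train_dffnn One-row model summary.
#' @export
glance.dffnn <- function(x, ...) {
  tibble(
    input_dim = x$shape$input_dim,
    width = x$shape$width,
    depth = x$shape$depth,
    n_parameters = sum(purrr::map_dbl(x$layers,
                                      ~ length(.x$W) + length(.x$b))),
    trained = x$trained,
    diverged = x$diverged,
    final_loss = if (length(x$loss_history)) tail(x$loss_history, 1) else NA_real_,
    algorithm = if (is.null(x$config)) NA_character_ else x$config$algorithm,
    learning_rate = if (is.null(x$config)) NA_real_ else x$config$learning_rate)
}

#' @export
print.dffnn <- function(x, ...) {
  cat(sprintf("<dffnn> %d -> [%d x %d] -> 1 (%s)\n",
              x$shape$input_dim, x$shape$width, x$shape$depth,
              if (x$trained) paste0("trained, ", x$config$algorithm) else "untrained"))
  invisible(x)
}
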