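# Independent oracles and small fixture builders used across the suite.

# Exhaustive path-enumeration oracle for reverse synapse weights: for every
# input-to-output path, multiply the traversed weights and the reciprocal of
# each traversed layer's width, then sum per input neuron. Deliberately
# recursive and brute-force — it shares no code with reverse_weights().
rsw_enumerate <- function(layers) {
  n_in <- nrow(layers[[1]]$W)
  vapply(seq_len(n_in), function(i) {
    walk <- function(layer, neuron) {
      if (layer > length(layers)) return(1)
      W <- layers[[layer]]$W
      width <- ncol(W)
      total <- 0
      for (j in seq_len(width)) {
        total <- total + (W[neuron, j] / width) * walk(layer + 1, j)
      }
      total
    }
    walk(1, i)
  }, numeric(1))
}

# Random layer stack with the package's weight convention.
random_layers <- function(dims, seed = 1) {
  withr::with_seed(seed, {
    lapply(seq_len(length(dims) - 1), function(l) {
      list(W = matrix(rnorm(dims[l] * dims[l + 1]), dims[l], dims[l + 1]),
           b = rnorm(dims[l + 1]))
    })
  })
}

# Wrap a layer stack as a dffnn so package functions accept it.
as_dffnn <- function(layers, feature_names = NULL) {
  structure(list(
    shape = dffnn_shape(nrow(layers[[1]]$W), spread = 1,
                        depth = max(1L, length(layers) - 1L)),
    layers = layers, trained = TRUE, loss_history = numeric(0),
    diverged = FALSE, config = NULL, seed = 1L,
    feature_names = feature_names), class = "dffnn")
}

# Purely linear forward pass (no activations), the reference map for the
# gradient-proportionality property.
linear_forward <- function(layers, x) {
  a <- matrix(x, nrow = 1)
  for (l in layers) a <- a %*% l$W + matrix(l$b, 1)
  as.numeric(a)
}

numeric_gradient <- function(f, x, h = 1e-6) {
  vapply(seq_along(x), function(i) {
    xp <- x; xp[i] <- xp[i] + h
    xm <- x; xm[i] <- xm[i] - h
    (f(xp) - f(xm)) / (2 * h)
  }, numeric(1))
}

# Small clean regression table: target exactly linear in the first feature.
make_linear_table <- function(n = 60, p = 4, seed = 1) {
  withr::with_seed(seed, {
    X <- matrix(rnorm(n * p), n, p)
    colnames(X) <- paste0("f", seq_len(p))
    d <- tibble::as_tibble(as.data.frame(X))
    d$dist <- 100 + 20 * X[, 1]
    as_feature_table(d, target = "dist")
  })
}

tiny_plan <- function(...) {
  defaults <- list(n_exp = 1L, n_epoch = 3L, c_lr = 2L,
                   lr_bounds = c(1e-4, 1e-2), spreads = 1, depths = 1L,
                   algorithms = "Adam", sweep_spread = 1, sweep_depth = 1L,
                   batch_size = 16L)
  do.call(ffdb_plan, utils::modifyList(defaults, list(...)))
}

# Numeric-content comparison for exported/re-read tables: integer columns
# legitimately come back as doubles, so compare values exactly but not types.
expect_same_content <- function(a, b) {
  expect_equal(names(a), names(b))
  for (cn in names(a)) {
    av <- a[[cn]]; bv <- b[[cn]]
    if (is.numeric(av)) {
      expect_identical(as.numeric(av), as.numeric(bv), label = cn)
    } else {
      expect_identical(av, bv, label = cn)
    }
  }
}
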