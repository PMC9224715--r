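test_that("model shapes resolve hidden widths from the spread factor", {
  s <- dffnn_shape(92, spread = 5, depth = 6)
  expect_equal(s$width, 460)
  expect_equal(s$depth, 6)

  s2 <- dffnn_shape(2, spread = 1, depth = 1)
  m <- build_dffnn(s2, seed = 1)
  dims <- lapply(m$layers, function(l) dim(l$W))
  expect_equal(dims, list(c(2L, 2L), c(2L, 1L)))  # 2 -> 2 -> 1

  expect_error(dffnn_shape(92, spread = 0.001, depth = 1),
               class = "gaitffdb_config_error")
})

test_that("initialization and training are deterministic under a fixed seed", {
  s <- dffnn_shape(4, spread = 2, depth = 2)
  m1 <- build_dffnn(s, seed = 42)
  m2 <- build_dffnn(s, seed = 42)
  expect_identical(m1$layers, m2$layers)
  m3 <- build_dffnn(s, seed = 43)
  expect_false(identical(m1$layers, m3$layers))

  ft <- make_linear_table(n = 50, p = 4)
  cfg <- train_config("Adam", 1e-3, n_epoch = 10, seed = 7)
  f1 <- train_dffnn(build_dffnn(s, 7), ft, cfg)
  f2 <- train_dffnn(build_dffnn(s, 7), ft, cfg)
  expect_identical(f1$loss_history, f2$loss_history)
  expect_identical(f1$layers, f2$layers)
})

test_that("a zero learning rate leaves the model untouched", {
  ft <- make_linear_table(n = 40, p = 3)
  s <- dffnn_shape(3, spread = 1, depth = 1)
  init <- build_dffnn(s, 1)
  fit <- train_dffnn(init, ft, train_config("SGD", 0, n_epoch = 8, seed = 1))
  expect_length(fit$loss_history, 8)
  # weights never move, so the epoch loss is constant up to the
  # single-precision summation-order jitter from reshuffled minibatches
  expect_identical(fit$layers, init$layers)
  expect_lt(diff(range(fit$loss_history)) / mean(fit$loss_history), 1e-5)
})

test_that("every configured algorithm reduces the loss on easy data", {
  ft <- make_linear_table(n = 80, p = 4)
  s <- dffnn_shape(4, spread = 2, depth = 1)
  lrs <- c(SGD = 1e-3, RMSProp = 1e-3, Adam = 1e-2, Adadelta = 1e-1,
           Adagrad = 1e-1, Adamax = 1e-2, Nadam = 1e-2)
  for (alg in ffdb_algorithms()) {
    fit <- train_dffnn(build_dffnn(s, 3), ft,
                       train_config(alg, lrs[[alg]], n_epoch = 60, seed = 3))
    expect_false(fit$diverged)
    expect_lt(tail(fit$loss_history, 1), fit$loss_history[1])
  }
})

test_that("the network fits noiseless linear data to a few percent", {
  ft <- make_linear_table(n = 200, p = 5, seed = 12)
  prep <- fit_preprocess(ft)
  tr <- apply_preprocess(prep, ft)
  fit <- fit_dffnn(tr, dffnn_shape(5, spread = 2, depth = 1),
                   train_config("Adam", 5e-3, n_epoch = 300, seed = 2))
  rmse <- sqrt(mean((predict(fit, tr) - tr$dist)^2))
  expect_lt(rmse, 0.05 * mean(tr$dist))
})

test_that("predictions follow closed forms and the stored weights", {
  # single linear neuron: w * x + b
  one <- as_dffnn(list(list(W = matrix(2.5), b = -1)))
  X <- matrix(c(-1, 0, 2), ncol = 1)
  expect_equal(predict(one, X), 2.5 * c(-1, 0, 2) - 1)

  # all-zero weights predict zero everywhere
  zero <- as_dffnn(list(list(W = matrix(0, 3, 2), b = c(0, 0)),
                        list(W = matrix(0, 2, 1), b = 0)))
  expect_equal(predict(zero, matrix(rnorm(9), 3, 3)), c(0, 0, 0))

  # hand-evaluated 2 -> 2 -> 1 forward pass with ReLU
  net <- as_dffnn(list(list(W = matrix(c(1, 0, -1, 1), 2, 2), b = c(0.5, 0)),
                       list(W = matrix(c(2, -3), 2, 1), b = 1)))
  x <- c(1, 2)
  h <- pmax(c(1 * 1 + 0 * 2 + 0.5, -1 * 1 + 1 * 2 + 0), 0)
  expect_equal(predict(net, matrix(x, 1, 2)), 2 * h[1] - 3 * h[2] + 1)

  # trained weights reproduce predict() through an independent forward pass
  ft <- make_linear_table(n = 30, p = 3)
  fit <- fit_dffnn(ft, dffnn_shape(3, spread = 2, depth = 2),
                   train_config("Adam", 1e-3, n_epoch = 5, seed = 9))
  X <- as.matrix(ft[, feature_names(ft)])
  manual <- X
  for (l in seq_along(fit$layers)) {
    manual <- manual %*% fit$layers[[l]]$W +
      matrix(fit$layers[[l]]$b, nrow(manual), length(fit$layers[[l]]$b),
             byrow = TRUE)
    if (l < length(fit$layers)) manual <- pmax(manual, 0)
  }
  expect_equal(predict(fit, ft), as.numeric(manual[, 1]), tolerance = 1e-6)
})

test_that("invalid configurations and dimension mismatches are rejected", {
  expect_error(train_config("AdamW", 1e-3), class = "gaitffdb_config_error")
  ft <- make_linear_table(n = 30, p = 3)
  fit <- fit_dffnn(ft, dffnn_shape(3, spread = 1, depth = 1),
                   train_config("SGD", 1e-3, n_epoch = 2, seed = 1))
  expect_error(predict(fit, matrix(0, 2, 5)),
               class = "gaitffdb_config_error")
  expect_error(train_dffnn(build_dffnn(dffnn_shape(5, 1, 1), 1), ft,
                           train_config("SGD", 1e-3, n_epoch = 2)),
               class = "gaitffdb_config_error")
})

test_that("exploding runs are flagged as diverged, not raised", {
  ft <- make_linear_table(n = 50, p = 4)
  fit <- fit_dffnn(ft, dffnn_shape(4, spread = 2, depth = 2),
                   train_config("SGD", 1e4, n_epoch = 30, seed = 5))
  expect_true(fit$diverged)
  expect_lte(length(fit$loss_history), 30)
})
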