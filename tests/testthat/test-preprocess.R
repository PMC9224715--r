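test_that("the 80/20 split produces the documented sizes and is seeded", {
  ft <- simulate_gait_cohort(n_patients = 500, n_features = 6, seed = 2)
  sp <- split_feature_table(ft, train_fraction = 0.8, seed = 9)
  expect_equal(nrow(sp$train), 400)
  expect_equal(nrow(sp$validation), 100)

  sp2 <- split_feature_table(ft, train_fraction = 0.8, seed = 9)
  expect_identical(sp$train$patient_id, sp2$train$patient_id)

  sp3 <- split_feature_table(ft, train_fraction = 0.8, seed = 10)
  expect_false(identical(sp$train$patient_id, sp3$train$patient_id))
})

test_that("splitting partitions the rows exactly once", {
  ft <- simulate_gait_cohort(n_patients = 10, n_features = 3,
                             n_informative = 2, seed = 4)
  for (seed in 1:5) {
    sp <- split_feature_table(ft, train_fraction = 0.8, seed = seed)
    ids <- c(sp$train$patient_id, sp$validation$patient_id)
    expect_setequal(ids, ft$patient_id)
    expect_equal(length(ids), 10)
  }
  expect_error(split_feature_table(ft, train_fraction = 1.2),
               class = "gaitffdb_config_error")
})

test_that("imputation uses the training mean and clipping follows mean +/- k*SD", {
  d <- tibble::tibble(f1 = c(1, 2, NA), f2 = c(0, 0, 0),
                      dist = c(10, 20, 30))
  ft <- as_feature_table(d, target = "dist")
  prep <- fit_preprocess(ft, outlier_k = 3)
  st <- tidy(prep)
  expect_equal(st$impute[st$feature == "f1"], 1.5)
  # constant feature: scale falls back to 1
  expect_equal(st$scale[st$feature == "f2"], 1)

  # hand-computed winsorizing: [0,0,0,100] at k = 1 clips 100 to 25 + 50 = 75
  d2 <- tibble::tibble(f = c(0, 0, 0, 100), dist = c(1, 2, 3, 4))
  ft2 <- as_feature_table(d2, target = "dist")
  prep2 <- fit_preprocess(ft2, outlier_k = 1)
  st2 <- tidy(prep2)
  expect_equal(st2$upper, mean(c(0, 0, 0, 100)) + sd(c(0, 0, 0, 100)))
  expect_equal(st2$upper, 75)
  clipped <- c(0, 0, 0, 75)
  expect_equal(st2$center, mean(clipped))
  expect_equal(st2$scale, sd(clipped))

  d3 <- tibble::tibble(f = c(NA_real_, NA_real_), dist = c(1, 2))
  ft3 <- as_feature_table(d3, target = "dist")
  err <- expect_error(fit_preprocess(ft3), class = "gaitffdb_data_error")
  expect_match(conditionMessage(err), "'f'")
})

test_that("applying to the training rows standardizes them exactly", {
  ft <- simulate_gait_cohort(n_patients = 80, n_features = 5,
                             missing_rate = 0.05, seed = 6)
  prep <- fit_preprocess(ft, outlier_k = 4)
  out <- apply_preprocess(prep, ft)
  for (f in feature_names(out)) {
    expect_lt(abs(mean(out[[f]])), 1e-9)
    expect_lt(abs(sd(out[[f]]) - 1), 1e-9)
  }
  # target is untouched (meters)
  expect_identical(out$distance_m, ft$distance_m)
})

test_that("a row at the training mean maps to the zero vector", {
  ft <- make_linear_table(n = 40, p = 3, seed = 8)
  prep <- fit_preprocess(ft, outlier_k = 4)
  st <- tidy(prep)
  row <- tibble::as_tibble(as.list(stats::setNames(st$center, st$feature)))
  row$dist <- 100
  probe <- as_feature_table(row, target = "dist")
  out <- apply_preprocess(prep, probe)
  expect_equal(unname(as.numeric(out[1, feature_names(out)])),
               rep(0, 3), tolerance = 1e-12)
})

test_that("preprocessing is fitted from training rows only", {
  ft <- simulate_gait_cohort(n_patients = 100, n_features = 4,
                             n_informative = 2, seed = 11)
  sp <- split_feature_table(ft, seed = 3)
  prep <- fit_preprocess(sp$train)
  # scrambling or dropping validation rows cannot change the fit
  prep_again <- fit_preprocess(sp$train)
  expect_identical(tidy(prep), tidy(prep_again))
  expect_error(
    apply_preprocess(prep, make_linear_table(n = 10, p = 2)),
    class = "gaitffdb_config_error")
})
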