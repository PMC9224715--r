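test_that("the relative error metric matches hand computation", {
  q <- msearr(c(10, 20), dist_avg = 150)
  expect_equal(q$msearr, 0.1)
  expect_equal(q$msearr_sd, sd(c(10, 20) / 150))
  expect_equal(q$n_exp, 2L)

  expect_equal(msearr(c(0, 0, 0), dist_avg = 120)$msearr, 0)
  expect_error(msearr(c(1, 2), dist_avg = -1),
               class = "gaitffdb_config_error")
})

test_that("the metric is scale invariant and applies the failed-run policy", {
  withr::with_seed(1, {
    for (i in 1:10) {
      rmse <- runif(5, 1, 30)
      davg <- runif(1, 50, 200)
      c <- runif(1, 0.1, 10)
      expect_equal(msearr(rmse, davg)$msearr,
                   msearr(c * rmse, c * davg)$msearr)
    }
  })
  # more failures than successes saturates the score at 1
  expect_equal(msearr(c(10), dist_avg = 100, n_failed = 2)$msearr, 1)
  expect_equal(msearr(numeric(0), dist_avg = 100, n_failed = 3)$msearr, 1)
  # up to half failures: average the usable runs
  expect_equal(msearr(c(10, 20), dist_avg = 150, n_failed = 2)$msearr, 0.1)
})

test_that("moving average smooths with truncated windows at the edges", {
  expect_equal(moving_average(c(5, 5, 5)), c(5, 5, 5))
  expect_equal(moving_average(7), 7)
  expect_equal(moving_average(c(1, 2, 3, 4, 5)), c(1.5, 2, 3, 4, 4.5))
  expect_equal(moving_average(c(1, 2, 3, 4, 5), window = 5),
               c(2, 2.5, 3, 3.5, 4))
  expect_error(moving_average(1:4, window = 2),
               class = "gaitffdb_config_error")
  # length preservation on random input
  withr::with_seed(2, {
    x <- rnorm(17)
    expect_length(moving_average(x), 17)
  })
})

test_that("error distribution fractions count and always partition", {
  ed <- error_distribution(c(100, 100, 100), c(100, 100, 100))
  expect_equal(unname(ed$fractions), c(1, 0, 0))

  ed2 <- error_distribution(c(110, 120, 130), c(100, 100, 100))
  expect_equal(unname(ed2$fractions), c(1, 1, 1) / 3)

  withr::with_seed(3, {
    for (i in 1:20) {
      m <- runif(50, 50, 200)
      p <- m + rnorm(50, sd = runif(1, 1, 40))
      ed <- error_distribution(p, m)
      expect_lt(abs(sum(ed$fractions) - 1), 1e-12)
      expect_equal(sum(ed$histogram$count), 50)
    }
  })
  expect_error(error_distribution(numeric(0), numeric(0)),
               class = "gaitffdb_data_error")
})

test_that("absolute and relative differences are absolute values", {
  d <- relative_differences(100, 110)
  expect_equal(d$abs_diff, 10)
  expect_equal(d$rel_diff, 0.10)
  expect_equal(relative_differences(c(50, 80), c(50, 80))$abs_diff, c(0, 0))

  withr::with_seed(4, {
    m <- runif(30, 50, 200)
    p <- m + rnorm(30, sd = 10)
    d <- relative_differences(m, p)
    expect_equal(d$abs_diff, abs(p - m))
    expect_equal(d$rel_diff, abs(p - m) / m)
    s <- summarise_differences(d)
    expect_equal(s$abs_mean, mean(abs(p - m)))
  })
  expect_error(relative_differences(c(-1, 2), c(1, 2)),
               class = "gaitffdb_data_error")
})

test_that("the agreement ICC matches an independent ANOVA computation", {
  withr::with_seed(5, {
    m <- runif(12, 80, 200)
    p <- m + rnorm(12, sd = 8)
  })
  res <- icc_agreement(m, p)

  # oracle: two-way ANOVA mean squares from stats::aov on the long layout
  long <- data.frame(y = c(m, p),
                     subject = factor(rep(seq_along(m), 2)),
                     rater = factor(rep(c("m", "p"), each = length(m))))
  ms <- summary(stats::aov(y ~ subject + rater, data = long))[[1]]$`Mean Sq`
  msr <- ms[1]; msc <- ms[2]; mse <- ms[3]
  n <- length(m); k <- 2
  oracle <- (msr - mse) / (msr + (k - 1) * mse + k / n * (msc - mse))
  expect_equal(res$icc, oracle, tolerance = 1e-10)
  expect_equal(res$ms_rows, msr, tolerance = 1e-10)
  expect_equal(res$ms_error, mse, tolerance = 1e-10)
  expect_true(res$conf_low <= res$icc && res$icc <= res$conf_high)

  # symmetric in the two raters
  swapped <- icc_agreement(p, m)
  expect_equal(swapped$icc, res$icc, tolerance = 1e-12)
})

test_that("ICC reaches 1 on identity and 0 on independent pairings", {
  m <- c(100, 120, 140, 160, 90)
  perfect <- icc_agreement(m, m)
  expect_equal(perfect$icc, 1)
  expect_equal(perfect$conf_low, 1)

  withr::with_seed(6, {
    big <- rnorm(10000, 137, 33)
    shuffled <- sample(big)
  })
  indep <- icc_agreement(big, shuffled)
  expect_lt(abs(indep$icc), 0.05)

  expect_error(icc_agreement(rep(1, 5), rep(1, 5)),
               class = "gaitffdb_data_error")
  expect_error(icc_agreement(c(1, 2), c(1, 2)),
               class = "gaitffdb_data_error")
})
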