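# Histogram fitting, means, group comparison, angle classification.

test_that("exponential histogram fit recovers the mean of exponential draws", {
  set.seed(31)
  x <- rexp(5000, rate = 1 / 13)
  fit <- fit_exponential_histogram(x, bin_width = 4)
  # oracle: the sample mean is the MLE of an exponential mean
  expect_equal(fit$t1, mean(x), tolerance = 0.5 / 13)
  expect_lt(abs(fit$t1 - 13), 0.5)
  expect_gt(fit$t1_se, 0)
  mle <- fit_exponential_histogram(x, method = "mle")
  expect_equal(mle$t1, mean(x), tolerance = 1e-12)
})

test_that("an exactly exponential histogram is recovered to high precision", {
  t1 <- 13; bw <- 4
  mids <- bw * (0:9) + bw / 2
  counts <- round(1e6 * exp(-mids / t1))
  values <- rep(mids, counts)
  fit <- fit_exponential_histogram(values, bin_width = bw)
  expect_lt(abs(fit$t1 - t1) / t1, 1e-4)
})

test_that("fit consistency: error shrinks as n grows", {
  errs <- sapply(c(1e2, 1e3, 1e4), function(n) {
    set.seed(1000 + n)
    mean(replicate(5, {
      abs(fit_exponential_histogram(rexp(n, 1 / 20))$t1 - 20)
    }))
  })
  expect_lt(errs[3], errs[1])
  expect_lt(errs[3], 1)
})

test_that("degenerate histograms are fit errors", {
  expect_error(fit_exponential_histogram(rep(5, 100)), "non-empty bins")
  expect_error(fit_exponential_histogram(rexp(5, 1)), "at least 10")
})

test_that("arithmetic mean and standard error", {
  m <- arithmetic_mean_se(c(1, 1, 2, 2))
  expect_equal(m$mean, 1.5)
  expect_equal(m$se, 0.2887, tolerance = 1e-3)
  expect_true(is.na(arithmetic_mean_se(3)$se))
  expect_equal(arithmetic_mean_se(rep(2, 5))$se, 0)
  expect_error(arithmetic_mean_se(numeric(0)), "empty")
})

test_that("t test matches the brute-force pooled formula on random samples", {
  set.seed(33)
  for (i in 1:100) {
    a <- rnorm(sample(2:12, 1), mean = runif(1, -2, 2), sd = runif(1, 0.5, 3))
    b <- rnorm(sample(2:12, 1), mean = runif(1, -2, 2), sd = runif(1, 0.5, 3))
    got <- compare_groups(a, b)
    want <- oracle_pooled_t(a, b)
    expect_equal(got$statistic, want$statistic, tolerance = 1e-9)
    expect_equal(got$p.value, want$p.value, tolerance = 1e-9)
  }
})

test_that("t test handles worked and degenerate cases", {
  got <- compare_groups(c(1, 2, 3), c(4, 5, 6))
  expect_equal(got$statistic, -3.674, tolerance = 1e-3)
  expect_equal(got$p.value, 0.0213, tolerance = 1e-2)
  same <- compare_groups(c(2, 2), c(2, 2))
  expect_equal(same$statistic, 0)
  expect_equal(same$p.value, 1)
  far <- compare_groups(rnorm(20), rnorm(20) + 100)
  expect_lt(far$p.value, 1e-4)
})

test_that("exponential fraction within a time", {
  expect_equal(exponential_fraction_within(13, 29), 0.8925, tolerance = 1e-3)
  expect_equal(exponential_fraction_within(42, 0), 0)
  expect_equal(exponential_fraction_within(3, 1e9), 1)
  expect_error(exponential_fraction_within(0, 5), "positive")
})

test_that("angle classifier reproduces the worked groupings", {
  cl <- classify_crossover_angles(c(22, 24, 26, 45, 47, 49))
  expect_equal(cl$small_mean, 24)
  expect_equal(cl$large_mean, 47)
  expect_length(cl$discarded, 0)
  # an angle 13 degrees from the rest of its group is discarded
  cl2 <- classify_crossover_angles(c(22, 24, 26, 45, 47, 49, 60))
  expect_equal(cl2$discarded, 60)
  expect_equal(cl2$large_mean, 47)
  cl3 <- classify_crossover_angles(c(24, 24, 24))
  expect_true(cl3$degenerate)
  expect_length(cl3$large, 0)
})

test_that("two-means split agrees with exhaustive enumeration of all partitions", {
  set.seed(35)
  for (i in 1:12) {
    n <- sample(4:12, 1)
    x <- sort(round(runif(n, 10, 80), 1))
    if (length(unique(x)) < 2) next
    sp <- decatr:::best_two_split(x)
    got_small <- x[seq_len(sp)]
    want <- oracle_best_partition(x)
    expect_equal(got_small, want$small)
  }
})

test_that("cohort summary uses the right estimator per feature", {
  set.seed(36)
  feats <- dplyr::bind_rows(
    tibble::tibble(feature = "secondary_lag", value = rexp(400, 1 / 13)),
    tibble::tibble(feature = "initial_lag", value = rexp(120, 1 / 48)),
    tibble::tibble(feature = "run_size", value = sample_run_size(1.8, 400)),
    tibble::tibble(feature = "run_rate", value = rnorm(400, 1.2, 0.2)),
    tibble::tibble(feature = "total_rate", value = rnorm(40, 0.05, 0.01))
  )
  feats$enzyme <- "topoIII"
  out <- summarize_cohort(feats)
  expect_setequal(out$feature, unique(feats$feature))
  expect_identical(
    out$estimator[out$feature %in% c("initial_lag", "secondary_lag")],
    rep("exponential_fit", 2))
  expect_identical(
    out$estimator[out$feature %in% c("run_size", "run_rate", "total_rate")],
    rep("arithmetic", 3))
  est <- out$estimate[out$feature == "secondary_lag"]
  expect_equal(est, 13, tolerance = 0.15)
  # round-trip within 2 se of the generating means
  for (f in c("secondary_lag", "initial_lag")) {
    row <- out[out$feature == f, ]
    truth <- c(secondary_lag = 13, initial_lag = 48)[[f]]
    expect_lt(abs(row$estimate - truth), 3 * row$error + 0.05 * truth)
  }
  expect_warning(summarize_cohort(
    tibble::tibble(feature = "run_size", value = c(1, 2))), "Only")
})
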