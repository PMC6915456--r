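test_that("moving average is a centered, edge-truncated smoother", {
  expect_equal(moving_average(rep(4.2, 30), 5), rep(4.2, 30))
  expect_equal(moving_average(c(0, 3, 0), 3), c(1.5, 1.0, 1.5))
  x <- rnorm(50)
  expect_equal(moving_average(x, 1), x)
  expect_error(moving_average(numeric(0), 3), "empty")
  expect_error(moving_average(1:5, 4))  # even window
})

test_that("filtering preserves the mean up to the edge-effect bound", {
  set.seed(3)
  for (rep in 1:25) {
    n <- sample(10:120, 1)
    w <- sample(c(3, 5, 7, 9), 1)
    x <- rnorm(n, sd = sample(1:5, 1))
    bound <- (w - 1) * diff(range(x)) / (2 * n)
    expect_lte(abs(mean(moving_average(x, w)) - mean(x)), bound + 1e-12)
  }
})

test_that("statistics reproduce hand-computed values", {
  expect_equal(compute_statistic("mean", c(1, 2, 3, 4)), 2.5)
  expect_equal(compute_statistic("rms", c(1, 2, 3, 4)), sqrt(30 / 4))
  expect_equal(compute_statistic("power", c(1, 2, 3)), 14 / 3)
  expect_equal(compute_statistic("peak_to_peak", c(1, 5, 2)), 4)
  expect_equal(compute_statistic("mean_derivative", c(1, 3, 6), dt = 1), 2.5)
  expect_equal(compute_statistic("mean_derivative", c(1, 3, 6), dt = 2), 1.25)
  expect_equal(compute_statistic("std", c(2, 4)), 1)  # population form
})

test_that("constant signals force the degenerate statistic values", {
  x <- rep(3, 40)
  expect_equal(compute_statistic("std", x), 0)
  expect_equal(compute_statistic("peak_to_peak", x), 0)
  expect_equal(compute_statistic("n_peaks", x), 0L)
  expect_equal(compute_statistic("peak_to_rms", x), 1)
  expect_equal(compute_statistic("rms", x), 3)
  expect_equal(compute_statistic("rms", -x), 3)
})

test_that("peak counting uses the interior-plateau convention", {
  expect_equal(compute_statistic("n_peaks", c(0, 1, 0, 2, 0)), 2L)
  expect_equal(compute_statistic("n_peaks", c(0, 2, 2, 0)), 1L)
  expect_equal(compute_statistic("n_peaks", c(5, 1, 1, 5)), 0L)  # valley
  expect_equal(compute_statistic("n_peaks", c(9, 1, 2)), 0L)     # endpoints
  expect_equal(compute_statistic("n_peaks", c(1, 2, 2)), 0L)     # end plateau
})

test_that("statistic preconditions raise named errors", {
  expect_error(compute_statistic("std", 5), "std")
  expect_error(compute_statistic("mean_derivative", 5), "mean_derivative")
  expect_error(compute_statistic("peak_to_rms", rep(0, 10)), "zero")
})

test_that("every statistic matches the brute-force oracle on random input", {
  set.seed(101)
  for (rep in 1:200) {
    n <- sample(2:120, 1)
    x <- round(rnorm(n, sd = sample(c(0.5, 2, 10), 1)), sample(0:3, 1))
    dt <- sample(c(0.5, 1, 2), 1)
    for (s in pain_statistics()) {
      got <- tryCatch(compute_statistic(s, x, dt = dt), error = function(e) NA)
      want <- tryCatch(oracle_stat(s, x, dt = dt), error = function(e) NA)
      if (is.na(want)) next
      expect_equal(got, want, tolerance = 1e-9,
                   info = sprintf("%s rep %d", s, rep))
    }
  }
})

test_that("rms is exactly the square root of power", {
  set.seed(7)
  for (rep in 1:50) {
    x <- rnorm(sample(1:60, 1), sd = 5)
    expect_identical(compute_statistic("rms", x),
                     sqrt(compute_statistic("power", x)))
    expect_equal(compute_statistic("rms", x)^2,
                 compute_statistic("power", x), tolerance = 1e-15)
  }
})

test_that("a full 8-channel segment yields 64 canonically named features", {
  b <- uniform_bundle(minutes = 1)
  fv <- extract_features(segment_streams(b)[[1]])
  expect_length(fv, 64L)
  expect_equal(names(fv), pain_feature_names())
  # order independence: shuffled channel list gives identical values
  seg <- segment_streams(b)[[1]]
  seg$samples <- seg$samples[sample(names(seg$samples))]
  expect_equal(extract_features(seg), fv)
})

test_that("missing channels shrink the vector; failures flag NA", {
  seg <- make_segment(list(HR = rnorm(60), RR = rnorm(60), GSR = rnorm(60),
                           TEMP = rnorm(60), ACC_Z = rnorm(60)))
  expect_length(extract_features(seg), 40L)
  # all-zero channel: peak_to_rms undefined -> NA, not zero
  seg0 <- make_segment(list(GYR_Y = rep(0, 60)))
  fv <- extract_features(seg0)
  expect_true(is.na(fv[["GYR_Y__peak_to_rms"]]))
  expect_equal(fv[["GYR_Y__std"]], 0)
})

test_that("STEPS is analysed as increments of the cumulative counter", {
  steps <- cumsum(c(0, rep(c(2, 0), 30)))  # alternating increments
  seg <- make_segment(list(STEPS = steps))
  fv_inc <- extract_features(seg, filter_config(window = 1))
  fv_raw <- extract_features(seg, filter_config(window = 1,
                                                steps_as_increments = FALSE))
  expect_equal(fv_inc[["STEPS__mean"]], 1)          # mean increment
  expect_gt(fv_inc[["STEPS__n_peaks"]], 0)
  expect_equal(fv_raw[["STEPS__n_peaks"]], 0)       # monotone counter
  expect_gt(fv_raw[["STEPS__mean"]], 20)
})

test_that("coupling-free zero-noise segments have zero spread features", {
  cfg <- tiny_sim_config(
    seed = 12, n_sessions = 1,
    coupling = stats::setNames(rep(0, 8), pain_channels()),
    noise_sd = stats::setNames(rep(0, 8), pain_channels()))
  b <- generate_session(cfg, 1)
  fv <- extract_features(segment_streams(b)[[1]])
  stds <- fv[grep("__std$", names(fv))]
  expect_true(all(stds == 0))
})
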