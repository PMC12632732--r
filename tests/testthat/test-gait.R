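test_that("heel strikes on noiseless simulation match ground truth within one sample", {
  g <- simulate_gait(noiseless_gait_config())
  truth <- attr(g$right, "ground_truth")
  s <- detect_heel_strikes(g$right, 1.2)
  dev <- vapply(s, function(i) min(abs(i - truth$strike_samples)),
                numeric(1))
  expect_lte(max(dev), 1)
  expect_true(all(diff(s) > 0))
})

test_that("constant AP signal raises an insufficient-data error", {
  flat <- marker_trajectory(
    data.frame(time_s = (0:199) / 100, x_mm = 0, y_mm = 5, z_mm = 0),
    sample_rate = 100, side = "right")
  expect_error(detect_heel_strikes(flat, 1.2), "insufficient|peaks")
})

test_that("small additive noise does not change the strike count", {
  g0 <- simulate_gait(noiseless_gait_config(n_strides = 30))
  n0 <- length(detect_heel_strikes(g0$right, 1.2))
  excursion <- 600
  for (seed in 1:5) {
    set.seed(seed)
    noisy <- g0$right
    noisy$y_mm <- noisy$y_mm + rnorm(nrow(noisy), 0, 0.01 * excursion)
    expect_equal(length(detect_heel_strikes(noisy, 1.2)), n0)
  }
})

test_that("heel lifts interleave strikes and equal an exhaustive argmin scan", {
  cfg <- gait_sim_config(cv_stride_time = 4, cv_stride_length = 4,
                         n_strides = 25, seed = 3L)
  g <- simulate_gait(cfg)
  s <- detect_heel_strikes(g$right, 1.3)
  l <- detect_heel_lifts(g$right, s)
  expect_equal(length(l), length(s) - 1L)
  # interleaving: exactly one lift strictly between consecutive strikes
  expect_true(all(l > s[-length(s)] & l < s[-1]))
  # oracle: brute-force scan of every between-strike window
  oracle <- vapply(seq_len(length(s) - 1L), function(k) {
    win <- (s[k] + 1L):(s[k + 1L] - 1L)
    win[which.min(g$right$y_mm[win])]
  }, integer(1))
  expect_equal(l, oracle)
})

test_that("a plateau minimum resolves to the earliest sample", {
  ap <- c(5, 3, 1, -2, -2, -2, 1, 3, 5)
  traj <- marker_trajectory(
    data.frame(time_s = (seq_along(ap) - 1) / 100, x_mm = 0, y_mm = ap,
               z_mm = 0),
    sample_rate = 100, side = "right")
  expect_equal(detect_heel_lifts(traj, c(1L, 9L)), 4L)
})

test_that("stride times are successive strike differences in ms", {
  expect_equal(compute_stride_times(c(1L, 121L, 241L), 100),
               c(1200, 1200))
  expect_equal(compute_stride_times(c(10L, 140L), 100), 1300)
  g <- simulate_gait(noiseless_gait_config())
  s <- detect_heel_strikes(g$right, 1.2)
  expect_equal(unique(compute_stride_times(s, 100)), 1200)
})

test_that("stride lengths equal the lift-to-strike AP distance", {
  g <- simulate_gait(noiseless_gait_config())
  s <- detect_heel_strikes(g$right, 1.2)
  l <- detect_heel_lifts(g$right, s)
  lens <- compute_stride_lengths(g$right, l, s)
  expect_equal(unique(round(lens, 9)), 600)
  # a lift with no following strike is an error
  expect_error(compute_stride_lengths(g$right, max(s) + 5L, s),
               "no following strike")
})

test_that("non-positive stride lengths are retained and flagged", {
  ap <- c(0, -5, 10, -5, 0, 10)
  traj <- marker_trajectory(
    data.frame(time_s = (seq_along(ap) - 1) / 100, x_mm = 0, y_mm = ap,
               z_mm = 0),
    sample_rate = 100, side = "right")
  # "lift" at a sample whose following strike is lower: negative length
  expect_warning(lens <- compute_stride_lengths(traj, 3L, c(1L, 4L, 6L)),
                 "flagged")
  expect_lt(lens[1], 0)
  expect_equal(attr(lens, "flagged"), 1L)
})

test_that("step widths use the lateral separation at right heel strikes", {
  mk <- function(ml) marker_trajectory(
    data.frame(time_s = (0:99) / 100, x_mm = ml, y_mm = sin(1:100),
               z_mm = 0), sample_rate = 100, side = "left")
  expect_equal(unique(compute_step_widths(mk(-100), mk(100), c(10L, 50L))),
               200)
  expect_equal(unique(compute_step_widths(mk(30), mk(30), c(10L, 50L))), 0)
  expect_warning(w <- compute_step_widths(mk(-100), mk(100), c(10L, 300L)),
                 "skipped")
  expect_equal(length(w), 1L)
})

test_that("gait summary computes sample-SD CV% and rejects degenerate input", {
  s <- summarize_gait(rep(1200, 20), rep(600, 20), rep(200, 20))
  expect_equal(s$cv_stride_time, 0)
  expect_equal(s$cv_stride_length, 0)
  s2 <- suppressWarnings(summarize_gait(c(1, 2, 3), c(1, 2, 3), c(1, 2, 3)))
  expect_equal(s2$mean_stride_time, 2)
  expect_equal(s2$cv_stride_time, 50)
  expect_error(summarize_gait(numeric(0), 1, 1), "empty")
  expect_warning(summarize_gait(rep(1200, 3), rep(600, 3), rep(200, 3)),
                 "strides")
})

test_that("gait metrics are invariant to AP and ML translations", {
  g <- simulate_gait(gait_sim_config(n_strides = 30, seed = 4L))
  base <- analyze_gait(g$left, g$right)$metrics
  shifted <- g
  shifted$right$y_mm <- shifted$right$y_mm + 500
  shifted$left$y_mm <- shifted$left$y_mm + 500
  shifted$right$x_mm <- shifted$right$x_mm + 75
  shifted$left$x_mm <- shifted$left$x_mm + 75
  moved <- analyze_gait(shifted$left, shifted$right)$metrics
  expect_equal(moved, base)
})

test_that("noisy gait recovery stays within Monte-Carlo error of the draws", {
  cfg <- gait_sim_config(cv_stride_time = 3, cv_stride_length = 3,
                         cv_step_width = 9, n_strides = 200, seed = 21L)
  g <- simulate_gait(cfg)
  truth <- attr(g$right, "ground_truth")
  res <- analyze_gait(g$left, g$right, expected_stride_time = 1.3)
  # means within 3 standard errors of the configured values
  se_t <- cfg$mean_stride_time * 0.03 / sqrt(200) * 1000
  expect_lt(abs(res$metrics$mean_stride_time - 1300), 3 * se_t)
  se_l <- cfg$mean_stride_length * 0.03 / sqrt(200)
  expect_lt(abs(res$metrics$mean_stride_length - 1237), 3 * se_l + 11)
  # CV of detected stride times tracks the CV of the retained draws
  drawn_cv <- cv_percent(truth$stride_times_s)
  expect_lt(abs(res$metrics$cv_stride_time - drawn_cv), 0.5)
})
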