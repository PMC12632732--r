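test_that("band-pass filter preserves the passband and rejects DC and 60 Hz", {
  fs <- 512
  t <- seq(0, 20, by = 1 / fs)
  x <- rbind(sin(2 * pi * 10 * t), sin(2 * pi * 60 * t), rep(3, length(t)))
  eeg <- eeg_continuous(x, fs, c("Cz", "Pz", "Fz"))
  f <- suppressWarnings(bandpass_filter(eeg))
  mid <- seq(3000, 7000)   # away from edge transients
  gain10 <- sd(f$data[1, mid]) / sd(x[1, mid])
  gain60 <- sd(f$data[2, mid]) / sd(x[2, mid])
  expect_lt(abs(gain10 - 1), 0.05)
  expect_lt(20 * log10(gain60), -20)
  expect_lt(mean(abs(f$data[3, mid])), 0.05)  # DC rejected
  # zero net phase: passband sinusoid stays aligned with the input
  expect_gt(cor(f$data[1, mid], x[1, mid]), 0.999)
})

test_that("band-pass filter errors when the signal cannot support padding", {
  eeg <- eeg_continuous(matrix(rnorm(2 * 50), 2), 512, c("Cz", "Pz"))
  expect_error(bandpass_filter(eeg, order = 60), "too short")
})

test_that("average reference zeroes the channel sum and is idempotent", {
  set.seed(1)
  eeg <- eeg_continuous(matrix(rnorm(8 * 100), 8), 512, paste0("ch", 1:8))
  ar <- average_reference(eeg)
  expect_lt(max(abs(colSums(ar$data))), 1e-10)
  expect_equal(average_reference(ar)$data, ar$data)
  # two channels at +1 / -1 are already average-referenced
  two <- eeg_continuous(rbind(rep(1, 10), rep(-1, 10)), 512, c("a", "b"))
  expect_equal(average_reference(two)$data, two$data)
  # all-identical channels collapse to zero
  same <- eeg_continuous(matrix(4, 5, 10), 512, paste0("c", 1:5))
  expect_true(all(average_reference(same)$data == 0))
})

test_that("spherical-spline interpolation reconstructs smooth scalp fields", {
  pos <- electrode_positions()
  # constant potential is reproduced exactly by the spline's constant term
  const <- eeg_continuous(matrix(7, 64, 3), 512, pos$label)
  ic <- interpolate_bad_channels(const, c("Pz", "F3"))
  expect_equal(ic$data[pos$label == "Pz", ], rep(7, 3), tolerance = 1e-6)
  # smooth low-order field: leave-one-out error below 5%
  field <- 5 * pos$z + 2 * pos$x - 1.5 * pos$y
  eeg <- eeg_continuous(matrix(field, ncol = 1), 512, pos$label)
  for (ch in c("Cz", "FCz", "CPz", "C3")) {
    rec <- interpolate_bad_channels(eeg, ch)
    truth <- field[pos$label == ch]
    expect_lt(abs(rec$data[pos$label == ch, 1] - truth) / abs(truth), 0.05)
  }
  # leave-one-out across many channels correlates > 0.95 with the truth
  inner <- pos$label[pos$theta_deg < 60]
  loo <- vapply(inner, function(ch) {
    interpolate_bad_channels(eeg, ch)$data[pos$label == ch, 1]
  }, numeric(1))
  expect_gt(cor(loo, field[match(inner, pos$label)]), 0.95)
  expect_error(interpolate_bad_channels(eeg, "XX9"), "unknown")
})

test_that("flag_bad_channels spots flatlines and gross power outliers", {
  set.seed(2)
  pos <- electrode_positions()
  dat <- matrix(rnorm(64 * 500), 64)
  dat[5, ] <- 0                       # flatline
  dat[10, ] <- rnorm(500, 0, 400)     # gross outlier
  eeg <- eeg_continuous(dat, 512, pos$label)
  flagged <- flag_bad_channels(eeg)
  expect_true(all(pos$label[c(5, 10)] %in% flagged))
  expect_lt(length(flagged), 6)
})

test_that("epoching yields 461 samples at 512 Hz with baseline removal", {
  fs <- 512
  n <- fs * 4
  dat <- matrix(rnorm(2 * n), 2)
  dat[2, ] <- 7                                  # constant channel
  ev <- data.frame(onset_s = c(0.05, 1.0, 2.0), condition = c("a", "a", "a"))
  eeg <- eeg_continuous(dat, fs, c("Cz", "Pz"), events = ev)
  expect_message(ep <- epoch_eeg(eeg), "dropped 1")
  expect_equal(dim(ep$data), c(2L, 461L, 2L))
  expect_equal(range(ep$times * fs), c(-51, 409))
  # constant channel is exactly zero after baseline subtraction
  expect_true(all(abs(ep$data[2, , ]) < 1e-12))
  expect_equal(attr(ep, "n_dropped"), 1L)
})

test_that("epoching sorts trials by condition and response type", {
  fs <- 100
  eeg <- eeg_continuous(matrix(rnorm(300), 1), fs, "Cz")
  ev <- data.frame(onset_s = c(1.0, 1.5, 2.0),
                   condition = c("W-NF-T", "S-NF-T", "S-NF-T"),
                   response_type = c("Hit", "CR", "Hit"))
  ep <- epoch_eeg(eeg, ev, window = c(-100, 300), baseline = NULL)
  expect_equal(ep$labels$condition, c("S-NF-T", "S-NF-T", "W-NF-T"))
  expect_equal(ep$labels$response_type, c("CR", "Hit", "Hit"))
})

test_that("grand averages weight participants, not trials, equally", {
  cfg <- erp_sim_config(channels = c("FCz", "CPz"), components = list(
    erp_component("P3", peak_latency = 400, peak_amplitude = 2)),
    n_trials_per_cell = 2)
  # participant A: 2 trials at gain 1; participant B: 6 trials at gain 2
  a <- simulate_erp_epochs(cfg, participant = "A", amp_scale = 1)
  b <- simulate_erp_epochs(cfg, participant = "B", amp_scale = 2,
                           n_trials = 6)
  ga <- grand_average(bind_epochs(a, b))
  expect_equal(ga$n, 2L)
  # unweighted mean of gains: (1 + 2) / 2 regardless of trial counts
  one <- grand_average(a)
  expect_equal(ga$data, one$data * 1.5, tolerance = 1e-12)
  # single participant with identical trials: average equals the trial
  expect_equal(one$data, a$data[, , 1])
})

test_that("difference waves subtract elementwise with metadata checks", {
  cfg <- erp_sim_config(channels = c("FCz", "CPz"), components = list(
    erp_component("P3", peak_latency = 400, peak_amplitude = 3)))
  hit <- grand_average(simulate_erp_epochs(cfg, response_type = "Hit"))
  expect_true(all(difference_wave(hit, hit)$data == 0))
  cr <- hit
  cr$data <- cr$data + 2
  expect_true(all(abs(difference_wave(cr, hit)$data - 2) < 1e-12))
  short <- erp_average(hit$data[, 1:100], hit$times[1:100], 512,
                       hit$channels)
  expect_error(difference_wave(short, hit), "match")
})

test_that("peak extraction finds signed extrema with boundary flags", {
  fs <- 512
  times <- (ceiling(-0.1 * fs):floor(0.8 * fs)) / fs
  lat <- 1000 * 123 / 512   # on-grid latency inside the P2 window
  wave <- 5 * exp(-0.5 * ((times * 1000 - lat) / 20)^2)
  avg <- erp_average(rbind(wave, -wave), times, fs, c("FCz", "CPz"))
  pk <- extract_peak(avg, component_spec("P2"))
  expect_equal(pk$amplitude, 5, tolerance = 1e-9)
  expect_equal(pk$latency_ms, lat)
  expect_false(pk$boundary)
  # negative component: minimum is found
  n2 <- extract_peak(avg, component_spec("N2", electrode = "CPz",
                                         window = c(100, 300)))
  expect_lt(n2$amplitude, 0)
  # monotone ramp peaks at the window edge and is flagged
  ramp <- erp_average(matrix(times, 1), times, fs, "CPz")
  rk <- extract_peak(ramp, component_spec("P3"))
  expect_true(rk$boundary)
  expect_equal(rk$latency_ms, 500, tolerance = 2)
  # group-adjusted window override is accepted
  td <- extract_peak(avg, component_spec("P3", window = c(363, 463)))
  expect_equal(td$component, "P3")
  expect_error(extract_peak(avg, component_spec("P3", electrode = "Oz")),
               "not present")
})

test_that("topographic window means handle constants, point windows, and sequences", {
  times <- (ceiling(-0.1 * 512):floor(0.8 * 512)) / 512
  avg <- erp_average(matrix(3.5, 2, length(times)), times, 512,
                     c("FCz", "CPz"))
  expect_equal(unname(topographic_window_mean(avg, 300, 25)), c(3.5, 3.5))
  # halfwidth 0 returns the nearest sample
  ramp <- erp_average(matrix(seq_along(times), 1), times, 512, "CPz")
  v0 <- topographic_window_mean(ramp, 250, 0)
  expect_equal(unname(v0), which.min(abs(times * 1000 - 250)))
  # the 100-600 ms difference-topography sequence yields 10 maps
  centers <- seq(125, 575, by = 50)
  expect_length(centers, 10L)
  maps <- vapply(centers, function(cc) topographic_window_mean(avg, cc, 25),
                 numeric(2))
  expect_equal(dim(maps), c(2L, 10L))
  expect_error(topographic_window_mean(avg, 850, 50), "outside")
})

test_that("the preprocessing chain commutes with scalar scaling", {
  set.seed(6)
  fs <- 256
  n <- fs * 6
  dat <- matrix(rnorm(4 * n), 4)
  ev <- data.frame(onset_s = c(1, 2.5, 4), condition = "S-NF-T",
                   response_type = "Hit", participant = "P01")
  run <- function(x) {
    eeg <- eeg_continuous(x, fs, c("FCz", "Cz", "CPz", "Pz"), events = ev)
    eeg <- suppressWarnings(bandpass_filter(eeg, order = 256))
    eeg <- average_reference(eeg)
    grand_average(epoch_eeg(eeg))$data
  }
  expect_equal(run(3 * dat), 3 * run(dat), tolerance = 1e-9)
})
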