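test_that("conduction velocity reproduces the worked distance/delay examples", {
  expect_equal(round(conduction_velocity(2, 15.5), 3), 0.129)
  expect_equal(round(conduction_velocity(2, 10.2), 3), 0.196)
  expect_equal(round(conduction_velocity(2, 25.3), 3), 0.079)
  expect_equal(round(conduction_velocity(2, 15), 3), 0.133)
  expect_equal(conduction_velocity(1, 1), 1)
  expect_error(conduction_velocity(2, 0), "positive")
  expect_error(conduction_velocity(0, 5), "positive")
})

test_that("conduction velocity is homogeneous in distance and delay", {
  set.seed(2)
  d <- runif(20, 0.5, 5); t <- runif(20, 1, 40)
  for (i in 1:20) {
    v <- conduction_velocity(d[i], t[i])
    expect_equal(conduction_velocity(2 * d[i], t[i]), 2 * v)
    expect_equal(conduction_velocity(d[i], 2 * t[i]), v / 2)
  }
})

test_that("percent reduction matches the published mean comparisons", {
  expect_equal(percent_reduction(0.196, 0.133)$percent_rounded, 32)
  expect_equal(percent_reduction(0.196, 0.129)$percent_rounded, 34)
  expect_equal(percent_reduction(0.194, 0.159)$percent_rounded, 18)
  expect_equal(percent_reduction(3, 3)$percent, 0)
  expect_error(percent_reduction(0, 1), "positive")
})

test_that("spike detection finds injected templates and rejects noise", {
  fs <- 20000
  set.seed(3)
  noise <- rnorm(fs)          # 1 s of pure noise
  expect_lte(nrow(detect_spikes(noise, fs, threshold_sd = 8)), 1L)

  tmpl <- larvaquant:::spike_template(fs)
  trace <- rnorm(fs, 0, 0.05)
  at <- 7001
  trace[at:(at + length(tmpl) - 1)] <- trace[at:(at + length(tmpl) - 1)] + tmpl
  det <- detect_spikes(trace, fs, threshold_sd = 5)
  expect_equal(nrow(det), 1L)
  peak_idx <- at - 1 + which.max(abs(tmpl))
  expect_lte(abs(det$index - peak_idx), 1)

  expect_error(detect_spikes(c(1, NA, 3), fs), "non-finite")
})

test_that("spike detection recalls simulated ground truth at moderate noise", {
  rec <- simulate_recording(ephys_config(duration_s = 30, noise_sd = 0.2,
                                         firing_rate_hz = 4, seed = 21))
  det <- detect_spikes(rec$trace1_volts, rec$sampling_hz, threshold_sd = 4)
  # recall: fraction of true spikes with a detection within 1 ms
  hits <- vapply(rec$truth$t1_s, function(t0) {
    any(abs(det$time_s - t0) < 2e-3)
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("amplitude sorting separates units and is order-invariant", {
  amps <- c(rep(1, 40), rep(2, 60))
  lab <- sort_units(amps, 2)
  expect_equal(lab, c(rep(1L, 40), rep(2L, 60)))

  set.seed(9)
  noisy <- c(rnorm(50, 1, 0.05), rnorm(50, 2, 0.05))
  perm <- sample(100)
  lab1 <- sort_units(noisy, 2)
  lab2 <- sort_units(noisy[perm], 2)
  expect_equal(lab1[perm], lab2)

  expect_equal(sort_units(c(3, 1, 2), 1), rep(1L, 3))
  expect_error(sort_units(c(1, 2), 3), "fewer spikes")
})

test_that("unit labels agree with simulated ground truth", {
  rec <- simulate_recording(ephys_config(duration_s = 30, n_units = 2,
                                         noise_sd = 0.1, seed = 14))
  det <- detect_spikes(rec$trace1_volts, rec$sampling_hz, threshold_sd = 4)
  lab <- sort_units(det$amplitude, 2)
  # align detections to truth within 1 ms
  truth_unit <- vapply(det$time_s, function(t0) {
    i <- which.min(abs(rec$truth$t1_s - t0))
    if (abs(rec$truth$t1_s[i] - t0) < 2e-3) rec$truth$unit[i] else NA_integer_
  }, integer(1))
  ok <- !is.na(truth_unit)
  expect_gte(mean(lab[ok] == truth_unit[ok]), 0.95)
})

test_that("greedy matching pairs shifted and jittered trains correctly", {
  t1 <- c(0.1, 0.5, 1.2, 2.0)
  m <- match_spikes(t1, t1 + 0.010, max_delay_ms = 20)
  expect_equal(m$pairs$delay_s, rep(0.010, 4))
  expect_equal(m$n_unmatched_e1, 0L)

  m0 <- match_spikes(t1, numeric(0), max_delay_ms = 20)
  expect_equal(nrow(m0$pairs), 0L)
  expect_equal(m0$n_unmatched_e1, 4L)

  # matching is invariant under a global time shift of both trains
  m_shift <- match_spikes(t1 + 100, t1 + 100.010, max_delay_ms = 20)
  expect_equal(m_shift$pairs$delay_s, m$pairs$delay_s)

  # jittered simulated trains: greedy matching equals the true pairing
  # when jitter is far below the minimum inter-spike interval
  rec <- simulate_recording(ephys_config(duration_s = 30, jitter_ms = 0.3,
                                         noise_sd = 0, seed = 6))
  m2 <- match_spikes(rec$truth$t1_s, rec$truth$t2_s, max_delay_ms = 40)
  expect_equal(nrow(m2$pairs), nrow(rec$truth))
  expect_equal(sort(m2$pairs$t2_s), sort(rec$truth$t2_s))
})

test_that("Grubbs pruning removes gross outliers and spares clean data", {
  clean <- c(0.19, 0.20, 0.21, 0.195, 0.205, 0.198, 0.202, 0.199)
  g0 <- grubbs_prune(clean)
  expect_equal(g0$n_removed, 0L)
  expect_equal(g0$values, clean)

  spiked <- c(clean, 10 * mean(clean))
  g1 <- grubbs_prune(spiked)
  expect_equal(g1$n_removed, 1L)
  expect_equal(g1$outliers, 10 * mean(clean))
  expect_equal(mean(g1$values), mean(clean))

  # identical values: nothing to remove, mean unchanged
  same <- rep(0.2, 6)
  expect_equal(grubbs_prune(same)$values, same)
})

test_that("recording velocity recovers known delays end to end", {
  # noise-free, jitter-free: estimate equals truth exactly
  rec0 <- simulate_recording(ephys_config(true_velocity_m_s = 0.2,
                                          jitter_ms = 0, noise_sd = 0,
                                          duration_s = 20, seed = 2))
  est0 <- estimate_velocity(rec0)
  expect_equal(est0$recording_mean_m_s, 0.2, tolerance = 1e-6)

  # ground-truth shift for delta_d = 2 mm at 0.2 m/s is 10 ms
  expect_equal((rec0$truth$t2_s - rec0$truth$t1_s)[1], 0.010)

  expect_error(recording_velocity(tibble::tibble(delay_s = 0.01),
                                  delta_d_mm = 2), "at least 3")
})

test_that("delay exceeding the trace duration is a configuration error", {
  cfg <- ephys_config(true_velocity_m_s = 0.001, electrode_distance_mm = 10,
                      duration_s = 5)
  expect_error(simulate_recording(cfg), "delay exceeds")
})

test_that("recording i/o round trip preserves the traces", {
  rec <- simulate_recording(ephys_config(duration_s = 0.5, seed = 12))
  stem <- file.path(withr::local_tempdir(), "rec")
  write_recording(rec, stem)
  back <- read_recording(stem)
  expect_equal(back$trace1_volts, rec$trace1_volts, tolerance = 1e-10)
  expect_equal(back$electrode_distance_mm, rec$electrode_distance_mm)
  expect_equal(nrow(back$truth), nrow(rec$truth))
})
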