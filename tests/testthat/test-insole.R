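make_rec <- function(ay, forces = NULL, fs = 100) {
  n <- length(ay)
  if (is.null(forces)) forces <- cbind(rep(0.5, n), rep(0.5, n))
  insole_recording(seq_len(n) / fs, ay, forces)
}

test_that("normalization follows the population-SD and max-1 conventions", {
  rec <- make_rec(c(1, 2, 3), cbind(c(1, 2, 4), c(1, 2, 4)))
  nr <- normalize_recording(rec)
  expect_equal(mean(nr$ay), 0)
  expect_equal(sqrt(mean(nr$ay^2)), 1)  # population SD convention
  expect_equal(nr$ay, (c(1, 2, 3) - 2) / sqrt(2 / 3))
  expect_equal(nr$total_force, c(0.25, 0.5, 1.0))
})

test_that("degenerate recordings cannot be normalized", {
  expect_error(normalize_recording(make_rec(rep(1, 10))), "constant")
  rec <- make_rec(rnorm(10), cbind(rep(0, 10), rep(0, 10)))
  expect_error(normalize_recording(rec), "positive maximum")
})

test_that("force subsets are validated and honored", {
  rec <- make_rec(rnorm(6), cbind(1:6, rep(1, 6), rep(2, 6)))
  nr <- normalize_recording(rec, force_subset = c(1, 3))
  expect_equal(nr$total_force, (1:6 + 2) / 8)
  expect_error(normalize_recording(rec, force_subset = c(1, 9)),
               "out of range")
})

test_that("low-pass filtering preserves DC and separates gait from noise bands", {
  expect_equal(lowpass_ay(rep(2.5, 100), 100), rep(2.5, 100),
               tolerance = 1e-4)
  fs <- 100
  t <- seq(0, 10, by = 1 / fs)
  x <- sin(2 * pi * 1 * t) + sin(2 * pi * 30 * t)
  y <- lowpass_ay(x, fs)
  fit <- function(sig, f0) {
    co <- stats::coef(stats::lm(sig ~ sin(2 * pi * f0 * t) +
                                  cos(2 * pi * f0 * t)))
    sqrt(sum(co[2:3]^2))
  }
  expect_lt(fit(y, 30) / fit(x, 30), 10^(-20 / 20))  # >= 20 dB down
  expect_equal(fit(y, 1), 1, tolerance = 0.05)       # passband within 5 %
})

test_that("single-sample spikes are removed by the median stage", {
  x <- rep(0, 100); x[50] <- 25
  y <- lowpass_ay(x, 100)
  expect_lt(max(abs(y)), 0.05)
})

test_that("cutoffs at or above Nyquist are rejected", {
  expect_error(lowpass_ay(rnorm(100), 100,
                          preprocess_config(butterworth_cutoff_hz = 50)),
               "Nyquist")
})

test_that("locking period of a pure sine is the half-period", {
  fs <- 100
  x <- sin(2 * pi * 1 * seq(0, 10, by = 1 / fs))
  lk <- locking_period(x, fs)
  expect_equal(lk$lockp_s, 0.5, tolerance = 0.02)
  expect_error(locking_period(abs(x) + 1, fs), "crossings")
})

test_that("locking period tracks half the stride time on simulated gait", {
  trial <- clean_trial(42)
  seg <- segment_insole(trial$insole)
  expect_equal(seg$lockp_s,
               mean(trial$truth$strides$stride_time_s) / 2,
               tolerance = 0.1)
})

test_that("stride peaks and counts are recovered on simulated gait", {
  for (seed in c(42, 7, 19)) {
    trial <- clean_trial(seed)
    seg <- segment_insole(trial$insole)
    expect_identical(seg$events$n_strides, trial$truth$n_strides)
    expect_identical(sum(seg$events$peaks$valid),
                     trial$truth$n_strides + 1L)
    # peak times sit on the simulated stride boundaries
    vt <- seg$events$peaks$time_s[seg$events$peaks$valid]
    expect_true(all(abs(vt - trial$truth$pulse_times_s) < 0.05))
  }
})

test_that("peaks closer than the locking period are invalidated", {
  fs <- 100
  lockp <- 1.0
  t <- seq(0, 6, by = 1 / fs)
  bump <- function(c0, h, w = 0.2)
    ifelse(abs(t - c0) <= w, h / 2 * (1 + cos(pi * (t - c0) / w)), 0)
  # second peak only 0.5 * lockP after the first
  x <- bump(2.0, 1) + bump(2.5, 0.9) + bump(4.0, 1) - 0.05
  ev <- detect_stride_peaks(x, fs, lockp)
  tms <- round(ev$peaks$time_s[ev$peaks$valid], 1)
  expect_true(2.0 %in% tms && 4.0 %in% tms)
  expect_false(2.5 %in% tms)
})

test_that("a single valid peak yields zero strides", {
  fs <- 100
  t <- seq(0, 4, by = 1 / fs)
  x <- ifelse(abs(t - 2) <= 0.2,
              0.5 * (1 + cos(pi * (t - 2) / 0.2)), 0) - 0.05
  ev <- detect_stride_peaks(x, fs, 0.8)
  expect_identical(sum(ev$peaks$valid), 1L)
  expect_identical(ev$n_strides, 0L)
})

test_that("gap-rule invalidation is idempotent and boundaries are sane", {
  trial <- noisy_trial(42)
  seg <- segment_insole(trial$insole)
  ev <- seg$events
  again <- tugkit:::apply_gap_rule(ev$peaks$time_s, ev$peaks$valid,
                                   ev$lockp_s, 2.5)
  expect_identical(again, ev$peaks$valid)
  b <- ev$stride_boundaries
  expect_true(all(b$end_s > b$start_s))
  expect_true(all(b$start_s[-1] >= b$end_s[-nrow(b)] - 1e-9))
  expect_true(all(b$start_s >= 0 & b$end_s <= max(trial$insole$time_s)))
  expect_identical(ev$n_strides, max(0L, sum(ev$peaks$valid) - 1L))
})

test_that("force validation counts stance/swing cycles and flags agreement", {
  trial <- clean_trial(42)
  seg <- segment_insole(trial$insole)
  expect_true(seg$validation$agreement)
  expect_identical(seg$validation$force_cycles, seg$validation$accel_peaks)

  # deleting one swing unload lowers the count by exactly one
  f <- seg$norm$total_force
  b0 <- trial$truth$pulse_times_s[3]
  kill <- trial$insole$time_s > b0 - 0.3 & trial$insole$time_s < b0 + 0.3
  f2 <- f; f2[kill] <- 1
  v2 <- validate_with_force(f2, seg$events, seg$norm$sample_rate_hz)
  expect_false(v2$agreement)
  expect_identical(v2$discrepancy, 1L)

  flat <- rep(1, length(f))
  v3 <- validate_with_force(flat, seg$events, seg$norm$sample_rate_hz)
  expect_identical(v3$force_cycles, 0L)
  expect_false(v3$agreement)
})

test_that("unnormalized force is rejected by the validators", {
  trial <- clean_trial(42)
  seg <- segment_insole(trial$insole)
  expect_error(validate_with_force(seg$norm$total_force * 3, seg$events,
                                   100), "normalized")
  expect_error(force_stride_times(seg$norm$total_force * 3, 100),
               "normalized")
})

test_that("sit-stand transitions are located from force with good overlap", {
  for (seed in c(42, 7)) {
    trial <- clean_trial(seed)
    seg <- segment_insole(trial$insole)
    expect_gte(interval_iou(seg$sts$sit_to_stand,
                            c(trial$truth$t0, trial$truth$t1)), 0.7)
    expect_gte(interval_iou(seg$sts$stand_to_sit,
                            c(trial$truth$t4, trial$truth$t5)), 0.7)
  }
})

test_that("degenerate force profiles yield transition errors", {
  expect_error(detect_sts_phases(rep(1, 500), 100), "no sit-to-stand")
  # monotone rise: sit-to-stand exists, stand-to-sit does not
  f <- seq(0.2, 1, length.out = 800)
  ph <- tryCatch(detect_sts_phases(f, 100), error = function(e) e)
  expect_s3_class(ph, "error")
  expect_match(conditionMessage(ph), "stand-to-sit")
})

test_that("gait parameters follow the cadence and speed definitions", {
  b <- data.frame(start_s = c(0, 1.2), end_s = c(1.2, 2.2))
  g <- compute_gait_parameters(b, c(1.3, 1.3))
  expect_equal(g$cadence_spm[1], 100)          # 60 * 2 / 1.2
  expect_equal(g$stride_speed_mps[2], 1.3)     # 1.3 m / 1.0 s
  expect_error(compute_gait_parameters(b, c(1.3)), "match")
  bad <- data.frame(start_s = 1, end_s = 1)
  expect_error(compute_gait_parameters(bad, 1), "positive")
})

test_that("stride counts survive moderate sensor noise", {
  ok <- 0L
  for (seed in 1:15) {
    trial <- simulate_tug(sim_params(seed = seed, radar_noise_sd_m = 0.05,
                                     ay_noise_sd = 0.33,
                                     force_noise_sd = 0.01))
    seg <- tryCatch(segment_insole(trial$insole),
                    error = function(e) NULL)
    if (!is.null(seg) &&
        abs(seg$events$n_strides - trial$truth$n_strides) <= 1L)
      ok <- ok + 1L
  }
  expect_gte(ok, 13L)
})

test_that("the stride overlapping the radar turn interval is labeled turn", {
  trial <- clean_trial(42)
  rep <- run_pipeline(trial$radar, trial$insole)
  turn_idx <- which(rep$strides$label == "turn")
  truth_turn <- which(trial$truth$strides$label == "turn")
  expect_identical(turn_idx, truth_turn)
})

test_that("insole CSV round-trips through the reader", {
  rec <- clean_trial(42)$insole
  path <- withr::local_tempfile(fileext = ".csv")
  write_insole_csv(rec, path)
  back <- read_insole_csv(path)
  expect_equal(back$ay, rec$ay)
  expect_equal(back$fsr2, rec$fsr2)
})
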