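test_that("radar_trace validates its invariants", {
  expect_error(radar_trace(c(0, 0.2, 0.1), c(1, 1, 1)), "increasing")
  expect_error(radar_trace(c(0, 0.2, 0.4), c(1, -1, 1)), "non-negative")
  expect_error(radar_trace(c(0, 0.2, 0.9), c(1, 1, 1)), "non-uniform")
  tr <- radar_trace(seq(0, 1, 0.2), rep(1, 6))
  expect_s3_class(tr, "radar_trace")
  expect_equal(attr(tr, "sample_interval_s"), 0.2)
})

test_that("a still subject is reported as quasi-static", {
  flat <- simulate_quasi_static(35, jitter_sd_m = 0.01, seed = 1)
  on <- detect_walk_onset(flat)
  expect_identical(on$verdict, "quasi-static")
})

test_that("motion slower than the threshold stays quasi-static", {
  tt <- seq(0, 35, 0.2)
  tr <- radar_trace(tt, 0.5 + 0.2 * tt)  # 0.2 m/s < 0.4 m/s threshold
  expect_identical(detect_walk_onset(tr)$verdict, "quasi-static")
})

test_that("walking onset is found near the start of the movement", {
  # 4 s seated, 1 s rise: walking proper begins at t = 5
  trial <- cached_trial("onset5", noise_free_params(42, sit_duration_s = 4))
  on <- detect_walk_onset(trial$radar)
  expect_identical(on$verdict, "onset")
  expect_gte(on$time_s, 4.4)
  expect_lte(on$time_s, 5.6)
})

test_that("traces shorter than the onset window are rejected", {
  tr <- radar_trace(seq(0, 2, 0.2), rep(0.5, 11))
  expect_error(detect_walk_onset(tr), "shorter than")
})

test_that("all six transition points are recovered on a noise-free trial", {
  trial <- clean_trial(42)
  ev <- segment_tug(trial$radar)
  errs <- event_errors(trial$truth, ev)
  expect_true(all(errs <= 2 / trial$truth$params$radar_rate_hz + 1e-9))
})

test_that("the walkway-end rule fixes T2 where the range reaches 3 m + D_pos", {
  # piecewise-linear toy trial crossing 3.5 m at exactly t = 9.0 s
  tt <- seq(0, 20, 0.2)
  d <- approx(x = c(0, 4, 5, 9, 10, 11, 14, 20),
              y = c(0.4, 0.4, 0.8, 3.5, 3.7, 3.7, 0.4, 0.4),
              xout = tt)$y
  ev <- segment_tug(radar_trace(tt, d))
  expect_lte(abs(ev$t2 - 9.0), 0.4)
})

test_that("trials that never reach the walkway end are flagged incomplete", {
  tt <- seq(0, 30, 0.2)
  d <- pmin(0.4 + 0.6 * pmax(0, tt - 4), 2.0)  # reaches only 2 m
  expect_error(segment_tug(radar_trace(tt, d)), "incomplete")
})

test_that("a quasi-static trace yields a no-activity error", {
  flat <- simulate_quasi_static(35, jitter_sd_m = 0.01, seed = 2)
  expect_error(segment_tug(flat), "no activity")
})

test_that("phases tile [T0, T5] without gaps", {
  ev <- segment_tug(clean_trial(42)$radar)
  expect_equal(ev$phases$start_s[-1], ev$phases$end_s[-5])
  expect_equal(sum(ev$phases$end_s - ev$phases$start_s), ev$t5 - ev$t0)
})

test_that("segmentation is invariant under a uniform time shift", {
  tr <- clean_trial(42)$radar
  ev1 <- segment_tug(tr)
  ev2 <- segment_tug(radar_trace(tr$time_s + 13.7, tr$distance_m))
  expect_equal(ev2$t0 - ev1$t0, 13.7, tolerance = 1e-9)
  expect_equal(ev2$t5 - ev1$t5, 13.7, tolerance = 1e-9)
})

test_that("increasing the standing offset never decreases T1", {
  tr <- clean_trial(42)$radar
  t1s <- vapply(c(0.15, 0.25, 0.3, 0.35), function(dqs)
    segment_tug(tr, segmentation_config(standing_offset_m = dqs))$t1,
    numeric(1))
  expect_true(all(diff(t1s) >= 0))
})

test_that("stride metrics recover displacement and speed", {
  tt <- seq(0, 10, 0.2)
  tr <- radar_trace(tt, 0.5 + 1.0 * tt)  # constant 1 m/s
  m <- radar_stride_metrics(tr, list(c(1, 2), c(4, 5)))
  expect_equal(m$length_m, c(1, 1), tolerance = 1e-9)
  expect_equal(m$speed_mps, c(1, 1), tolerance = 1e-9)

  trial <- clean_trial(42)
  walk <- trial$truth$strides[trial$truth$strides$label != "turn", ]
  mm <- radar_stride_metrics(trial$radar,
                             Map(c, walk$start_s, walk$end_s))
  expect_true(all(abs(mm$length_m - walk$stride_length_m) < 0.05))
})

test_that("degenerate stride intervals are rejected", {
  tr <- radar_trace(seq(0, 10, 0.2), rep(1, 51))
  expect_error(radar_stride_metrics(tr, list(c(2, 2))), "positive duration")
  expect_error(radar_stride_metrics(tr, list(c(9, 11))), "outside")
})

test_that("cubic resampling reproduces source points and linear traces", {
  tt <- seq(0, 10, 0.2)
  tr <- radar_trace(tt, 0.5 + 0.3 * tt)
  same <- resample_trace(tr, tt)
  expect_equal(same$distance_m, tr$distance_m, tolerance = 1e-12)
  mid <- resample_trace(tr, tt[-length(tt)] + 0.1)
  expect_equal(mid$distance_m, 0.5 + 0.3 * (tt[-length(tt)] + 0.1),
               tolerance = 1e-9)
})

test_that("cubic resampling of a smooth sinusoid stays near the analytic curve", {
  tt <- seq(0, 10, 0.2)
  f <- function(t) 2 + 0.5 * sin(2 * pi * 0.3 * t)
  tr <- radar_trace(tt, f(tt))
  dense <- seq(1, 9, 0.01)  # interior targets
  out <- resample_trace(tr, dense)
  expect_lt(max(abs(out$distance_m - f(dense))), 1e-3)
})

test_that("resampling refuses to extrapolate", {
  tr <- radar_trace(seq(0, 10, 0.2), rep(1, 51))
  expect_error(resample_trace(tr, c(-1, 2)), "xtrapolation")
})

test_that("radar CSV round-trips through the reader", {
  tr <- clean_trial(42)$radar
  path <- withr::local_tempfile(fileext = ".csv")
  write_radar_csv(tr, path)
  back <- read_radar_csv(path)
  expect_equal(back$time_s, tr$time_s)
  expect_equal(back$distance_m, tr$distance_m)
})
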