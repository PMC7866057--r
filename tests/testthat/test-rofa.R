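test_that("deviation ratio counts baseline standard deviations", {
  expect_equal(compute_ratio(1.2, 1.2, 0.1), 0)
  expect_equal(compute_ratio(1.4, 1.2, 0.1), 2)
  expect_equal(compute_ratio(1.0, 1.2, 0.1), 2)  # absolute value
  expect_error(compute_ratio(1, 1, 0), "positive")
})

test_that("per-parameter score drops 10 points per SD and clamps at 0", {
  expect_equal(compute_sk(0), 100)
  expect_equal(compute_sk(1), 90)
  expect_equal(compute_sk(15), 0)
  expect_error(compute_sk(-1), "non-negative")
})

test_that("composite score is a convex combination with validated weights", {
  expect_equal(compute_tug_score(rep(100, 4)), 100)
  expect_equal(compute_tug_score(c(80, 100), c(0.5, 0.5)), 90)
  expect_error(compute_tug_score(c(80, 100), c(0.5, 0.4)), "sum to 1")
  expect_error(compute_tug_score(numeric(0)), "no scores")
})

test_that("risk bands follow the printed ranges", {
  expect_identical(classify_risk(0), "very high")
  expect_identical(classify_risk(24), "very high")
  expect_identical(classify_risk(25), "high")
  expect_identical(classify_risk(49.9), "high")
  expect_identical(classify_risk(50), "medium")
  expect_identical(classify_risk(75), "low")
  expect_identical(classify_risk(99.99), "low")
  expect_identical(classify_risk(100), "very low")
  expect_error(classify_risk(101), "0, 100")
  expect_error(classify_risk(-2), "0, 100")
})

test_that("baselines pool strides across trials with sample SD", {
  t1 <- data.frame(stride_length_m = c(1.0, 1.2, 1.4))
  b <- build_baseline(list(t1))
  expect_equal(unname(b$means["stride_length_m"]), 1.2)
  expect_equal(unname(b$sds["stride_length_m"]), stats::sd(c(1, 1.2, 1.4)))
})

test_that("zero-variance parameters are flagged and excluded", {
  t1 <- data.frame(a = c(1, 1), b = c(1, 2))
  expect_warning(bl <- build_baseline(list(t1, t1)), "zero pooled variance")
  expect_false("a" %in% names(bl$means))
  expect_identical(attr(bl, "excluded"), "a")
  allflat <- data.frame(a = c(2, 2, 2))
  expect_error(suppressWarnings(build_baseline(list(allflat))),
               "positive variance")
})

test_that("simulated healthy baselines recover the planted stride length", {
  trials <- lapply(1:5, function(s) {
    tr <- clean_trial(s)
    walk <- tr$truth$strides[tr$truth$strides$label != "turn", ]
    data.frame(stride_length_m = walk$stride_length_m,
               stride_time_s = walk$stride_time_s)
  })
  b <- build_baseline(trials)
  expect_equal(unname(b$means["stride_length_m"]), 1.37, tolerance = 0.02)
})

test_that("a trial at the baseline means scores 100 / very low", {
  b <- baseline_stats(c(stride_length_m = 1.2, stride_time_s = 1.1,
                        cadence_spm = 109, stride_speed_mps = 1.1),
                      c(stride_length_m = 0.1, stride_time_s = 0.05,
                        cadence_spm = 5, stride_speed_mps = 0.1))
  trial <- data.frame(stride_length_m = rep(1.2, 4),
                      stride_time_s = rep(1.1, 4),
                      cadence_spm = rep(109, 4),
                      stride_speed_mps = rep(1.1, 4))
  r <- score_trial(trial, b)
  expect_equal(r$tug_score, 100)
  expect_identical(r$risk_band, "very low")
})

test_that("one SD off on every parameter scores 90 / low", {
  b <- baseline_stats(c(x = 10, y = 2), c(x = 1, y = 0.2))
  trial <- data.frame(x = rep(11, 3), y = rep(1.8, 3))
  r <- score_trial(trial, b)
  expect_equal(r$per_parameter$sk, c(90, 90))
  expect_equal(r$tug_score, 90)
  expect_identical(r$risk_band, "low")
})

test_that("scoring requires overlapping parameters", {
  b <- baseline_stats(c(x = 1), c(x = 1))
  expect_error(score_trial(data.frame(z = 1), b), "overlap")
})

test_that("the composite score is monotone in each deviation", {
  b <- baseline_stats(c(x = 10, y = 5), c(x = 1, y = 1))
  scores <- vapply(seq(0, 12, by = 0.5), function(dev)
    score_trial(data.frame(x = 10 + dev, y = 5), b)$tug_score, numeric(1))
  expect_true(all(diff(scores) <= 1e-12))
  expect_true(all(scores >= 0 & scores <= 100))
})

test_that("scores are invariant under rescaling a parameter and its baseline", {
  b1 <- baseline_stats(c(x = 10), c(x = 2))
  b2 <- baseline_stats(c(x = 1000), c(x = 200))
  r1 <- score_trial(data.frame(x = c(11, 13)), b1)
  r2 <- score_trial(data.frame(x = c(1100, 1300)), b2)
  expect_equal(r1$tug_score, r2$tug_score)
})

test_that("healthy simulated trials score above the low-risk floor against
           their own baseline", {
  trials <- lapply(1:5, function(s) {
    tr <- clean_trial(s)
    walk <- tr$truth$strides[tr$truth$strides$label != "turn", ]
    compute_gait_parameters(walk, walk$stride_length_m)
  })
  b <- build_baseline(trials)
  scores <- vapply(trials, function(t) score_trial(t, b)$tug_score,
                   numeric(1))
  expect_gt(mean(scores), 75)
})

test_that("baseline JSON round-trips", {
  b <- baseline_stats(c(stride_length_m = 1.3, stride_time_s = 1.1),
                      c(stride_length_m = 0.07, stride_time_s = 0.06))
  path <- withr::local_tempfile(fileext = ".json")
  write_baseline_json(b, path)
  back <- read_baseline_json(path)
  expect_equal(back$means, b$means)
  expect_equal(back$sds, b$sds)
})
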