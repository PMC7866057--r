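#' Segment an insole recording into strides
#'
#' Full insole-side chain: normalization (z-scored acceleration, total
#' force scaled to max 1 over the selected FSR subset), median +
#' zero-phase Butterworth low-pass, zero-crossing locking period, stride
#' peak detection with the gap rule, force-count validation and
#' force-based sit-to-stand / stand-to-sit detection.
#'
#' @param rec An [insole_recording()].
#' @param config Nested configuration list ([tug_config()]).
#' @param force_subset Optional FSR channel indices (sensor reduction).
#' @return List: `events` (`stride_events`), `gait` (per-stride
#'   parameters, lengths unset), `validation`, `sts`, `lockp_s`, `norm`.
#' @export
segment_insole <- function(rec, config = tug_config(), force_subset = NULL) {
  stopifnot(inherits(rec, "insole_recording"))
  pp <- do.call(preprocess_config, config$preprocess)
  norm <- normalize_recording(rec, force_subset)
  fs <- norm$sample_rate_hz
  ay_f <- lowpass_ay(norm$ay, fs, pp)
  lock <- locking_period(ay_f, fs)
  events <- detect_stride_peaks(ay_f, fs, lock$lockp_s, pp)
  validation <- validate_with_force(norm$total_force, events, fs)
  sts <- tryCatch(detect_sts_phases(norm$total_force, fs),
                  error = function(e) NULL)
  list(events = events, validation = validation, sts = sts,
       lockp_s = lock$lockp_s, zero_crossings = lock$zero_crossings,
       norm = norm, ay_filtered = ay_f)
}

# label each stride by its overlap with the radar phases; the stride
# overlapping the [T2, T3] turn interval is the turn stride
label_strides <- function(boundaries, events) {
  vapply(seq_len(nrow(boundaries)), function(i) {
    s <- boundaries$start_s[i]; e <- boundaries$end_s[i]
    if (min(e, events$t3) - max(s, events$t2) > 0.5 * (e - s)) "turn"
    else if (e <= events$t2 + 0.5 * (e - s)) "walk_forward"
    else "walk_back"
  }, character(1))
}

#' Run the full TUG analysis pipeline
#'
#' Orchestrates the complete analysis of one trial: segments the radar
#' trace into the five TUG phases, detects strides from the insole,
#' computes stride length by the three acceleration estimators and from
#' the radar displacement over the same stride intervals, derives the
#' per-stride gait parameters, compares insole and radar stride lengths
#' (paired Wilcoxon + RMSE), and scores the trial against a baseline when
#' one is given.
#'
#' @param radar A [radar_trace()] or path to a radar CSV.
#' @param insole An [insole_recording()] or path to an insole CSV.
#' @param config Nested configuration list ([tug_config()]).
#' @param baseline Optional [baseline_stats()] or path to a baseline JSON.
#' @param force_subset Optional FSR channel indices.
#' @param sl_approach Estimator used for the gait table (1, 2 or 3).
#' @return List of class `tug_report`: `events`, `insole` (segmentation),
#'   `strides` (per-stride table with all estimators, radar length and
#'   labels), `gait`, `comparison`, `rofa` (or NULL), `config_hash`.
#' @export
run_pipeline <- function(radar, insole, config = tug_config(),
                         baseline = NULL, force_subset = NULL,
                         sl_approach = 3L) {
  if (is.character(radar)) {
    if (!file.exists(radar)) stop("radar input: file not found: ", radar)
    radar <- read_radar_csv(radar)
  }
  if (is.character(insole)) {
    if (!file.exists(insole)) stop("insole input: file not found: ", insole)
    insole <- read_insole_csv(insole)
  }
  if (is.character(baseline)) baseline <- read_baseline_json(baseline)
  seg_cfg <- do.call(segmentation_config,
                     config$segmentation[names(config$segmentation) %in%
                                           names(formals(segmentation_config))])
  kf <- kf_config_of(config)
  consts <- calibration_constants(k1 = config$calibration$k1,
                                  k = config$calibration$k)

  events <- tryCatch(segment_tug(radar, seg_cfg, kf),
                     error = function(e)
                       stop("radar segmentation: ", conditionMessage(e)))
  ins <- tryCatch(segment_insole(insole, config, force_subset),
                  error = function(e)
                    stop("insole segmentation: ", conditionMessage(e)))
  b <- ins$events$stride_boundaries
  if (nrow(b) == 0L) stop("insole segmentation: no strides detected")

  sl <- vapply(1:3, function(a)
    stride_lengths_insole(insole, b, a, consts), numeric(nrow(b)))
  if (nrow(b) == 1L) sl <- matrix(sl, nrow = 1)
  radar_m <- radar_stride_metrics(radar, Map(c, b$start_s, b$end_s))
  strides <- data.frame(
    start_s = b$start_s, end_s = b$end_s,
    label = label_strides(b, events),
    sl_mean_abs_m = sl[, 1], sl_weinberg_m = sl[, 2],
    sl_scarlett_m = sl[, 3],
    sl_radar_m = radar_m$length_m,
    speed_radar_mps = radar_m$speed_mps)

  sl_used <- sl[, sl_approach]
  gait <- compute_gait_parameters(b, sl_used,
                                  config$rofa$steps_per_stride)
  comparison <- tryCatch(
    compare_stride_lengths(sl_used, radar_m$length_m),
    error = function(e) NULL)
  rofa <- if (!is.null(baseline))
    score_trial(gait, baseline, aggregate = config$rofa$aggregate)

  structure(list(events = events, insole = ins, strides = strides,
                 gait = gait, comparison = comparison, rofa = rofa,
                 sl_approach = sl_approach,
                 config_hash = config_hash(config)),
            class = "tug_report")
}

config_hash <- function(config) {
  s <- jsonlite::toJSON(config, auto_unbox = TRUE, digits = 10)
  # small stable polynomial hash; avoids an external digest dependency
  h <- 0
  for (b in utf8ToInt(s)) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

#' @export
print.tug_report <- function(x, ...) {
  cat("TUG analysis report\n")
  print(x$events)
  cat(sprintf("Strides: %d (lockP %.3f s); force validation: %s\n",
              x$insole$events$n_strides, x$insole$lockp_s,
              if (x$insole$validation$agreement) "agree" else
                sprintf("discrepancy %d", x$insole$validation$discrepancy)))
  print(x$strides, digits = 3)
  if (!is.null(x$comparison))
    cat(sprintf("Insole vs radar SL: RMSE %.3f m, Wilcoxon p = %.4f (%s)\n",
                x$comparison$rmse_m, x$comparison$wilcoxon$p_value,
                if (x$comparison$significant) "significant at 0.05"
                else "not significant"))
  if (!is.null(x$rofa)) print(x$rofa)
  invisible(x)
}

#' Write a pipeline report to JSON
#'
#' @param report A `tug_report` from [run_pipeline()].
#' @param path Output path.
#' @export
write_report_json <- function(report, path) {
  stopifnot(inherits(report, "tug_report"))
  ev <- report$events
  obj <- list(
    events = list(t0 = ev$t0, t1 = ev$t1, t2 = ev$t2, t3 = ev$t3,
                  t4 = ev$t4, t5 = ev$t5, phases = ev$phases),
    n_strides = report$insole$events$n_strides,
    lockp_s = report$insole$lockp_s,
    validation = report$insole$validation,
    strides = report$strides,
    gait = report$gait,
    comparison = if (!is.null(report$comparison)) list(
      statistic = report$comparison$wilcoxon$statistic,
      p_value = report$comparison$wilcoxon$p_value,
      n_pairs = report$comparison$wilcoxon$n_pairs,
      rmse_m = report$comparison$rmse_m,
      significant = report$comparison$significant),
    rofa = if (!is.null(report$rofa)) list(
      per_parameter = report$rofa$per_parameter,
      tug_score = report$rofa$tug_score,
      risk_band = report$rofa$risk_band),
    config_hash = report$config_hash)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}
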