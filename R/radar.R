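#' Radar range trace
#'
#' A uniformly sampled time series of radar-to-subject range. Validates
#' strictly increasing time, non-negative range, and uniform sampling
#' within tolerance.
#'
#' @param time_s Time stamps in seconds (strictly increasing).
#' @param distance_m Range in meters (>= 0).
#' @return A data.frame of class `radar_trace` with columns `time_s`,
#'   `distance_m` and a `sample_interval_s` attribute.
#' @export
radar_trace <- function(time_s, distance_m) {
  time_s <- as.numeric(time_s)
  distance_m <- as.numeric(distance_m)
  stopifnot(length(time_s) == length(distance_m), length(time_s) >= 2L,
            all(is.finite(time_s)), all(is.finite(distance_m)))
  dt <- diff(time_s)
  if (any(dt <= 0)) stop("time_s must be strictly increasing")
  if (any(distance_m < 0)) stop("distance_m must be non-negative")
  ts <- stats::median(dt)
  if (max(abs(dt - ts)) > 0.05 * ts)
    stop("non-uniform sampling beyond tolerance")
  structure(data.frame(time_s = time_s, distance_m = distance_m),
            sample_interval_s = ts,
            class = c("radar_trace", "data.frame"))
}

#' Read / write a radar trace CSV
#'
#' CSV with header `time_s,distance_m`.
#'
#' @param path File path.
#' @return `read_radar_csv` returns a [radar_trace()].
#' @export
read_radar_csv <- function(path) {
  df <- utils::read.csv(path)
  if (!all(c("time_s", "distance_m") %in% names(df)))
    stop("radar CSV must have columns time_s,distance_m")
  radar_trace(df$time_s, df$distance_m)
}

#' @rdname read_radar_csv
#' @param trace A [radar_trace()].
#' @export
write_radar_csv <- function(trace, path) {
  stopifnot(inherits(trace, "radar_trace"))
  utils::write.csv(as.data.frame(trace)[, c("time_s", "distance_m")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Segmentation settings for the radar TUG trace
#'
#' @param radar_offset_m Radar-to-chair distance D_pos (m).
#' @param walk_distance_m TUG walkway length (m).
#' @param standing_offset_m Chair-to-standing distance d_qs (m).
#' @param velocity_threshold_mps Walking-onset velocity threshold (m/s).
#' @param onset_window_s Accumulation / look-back window (s).
#' @param quasi_static_timeout_s Horizon after which a still trace is
#'   declared quasi-static (s).
#' @param turn_tolerance_m Range tolerance bounding the turn plateau (m),
#'   one radar range-resolution cell by default.
#' @param sit_tolerance_m Range tolerance for the return to the chair at
#'   the end of stand-to-sit (m).
#' @return An object of class `segmentation_config`.
#' @export
segmentation_config <- function(radar_offset_m = 0.5,
                                walk_distance_m = 3.0,
                                standing_offset_m = 0.3,
                                velocity_threshold_mps = 0.4,
                                onset_window_s = 3.0,
                                quasi_static_timeout_s = 30.0,
                                turn_tolerance_m = 0.1,
                                sit_tolerance_m = 0.03) {
  vals <- c(radar_offset_m, walk_distance_m, standing_offset_m,
            velocity_threshold_mps, onset_window_s, quasi_static_timeout_s,
            turn_tolerance_m, sit_tolerance_m)
  stopifnot(all(is.finite(vals)), all(vals > 0))
  if (walk_distance_m <= standing_offset_m)
    stop("walk_distance_m must exceed standing_offset_m")
  structure(
    list(radar_offset_m = radar_offset_m,
         walk_distance_m = walk_distance_m,
         standing_offset_m = standing_offset_m,
         velocity_threshold_mps = velocity_threshold_mps,
         onset_window_s = onset_window_s,
         quasi_static_timeout_s = quasi_static_timeout_s,
         turn_tolerance_m = turn_tolerance_m,
         sit_tolerance_m = sit_tolerance_m),
    class = "segmentation_config")
}

# KF kinematics of a trace, reusing the trace's own sample interval
trace_kinematics <- function(trace, kf = NULL) {
  ts <- attr(trace, "sample_interval_s")
  if (is.null(kf)) kf <- filter_config(sample_interval_s = ts)
  if (abs(kf$sample_interval_s - ts) > 0.05 * ts)
    kf$sample_interval_s <- ts
  estimate_kinematics(trace$distance_m, kf)
}

# first index >= from where `ok` holds at `persist` consecutive samples
first_sustained <- function(ok, from, persist = 2L) {
  n <- length(ok)
  if (from > n) return(NA_integer_)
  run <- 0L
  for (i in seq(from, n)) {
    run <- if (isTRUE(ok[i])) run + 1L else 0L
    if (run >= persist) return(i - persist + 1L)
  }
  NA_integer_
}

#' Detect the onset of walking in a radar trace
#'
#' Estimates velocity with the Kalman filter and looks for the first sample
#' whose speed reaches the onset threshold. If the speed stays below the
#' threshold over the whole quasi-static horizon the trace is declared
#' quasi-static (sitting or standing still).
#'
#' @param trace A [radar_trace()] of duration at least `onset_window_s`.
#' @param config A [segmentation_config()].
#' @param kf Optional [filter_config()]; defaults to the trace's rate.
#' @return A list with `verdict` ("onset" or "quasi-static"), `time_s`
#'   (onset time, `NA` when quasi-static) and `index`.
#' @export
detect_walk_onset <- function(trace, config = segmentation_config(),
                              kf = NULL) {
  stopifnot(inherits(trace, "radar_trace"),
            inherits(config, "segmentation_config"))
  dur <- trace$time_s[nrow(trace)] - trace$time_s[1]
  if (dur < config$onset_window_s)
    stop("trace shorter than onset window")
  kin <- trace_kinematics(trace, kf)
  horizon <- trace$time_s[1] + config$quasi_static_timeout_s
  in_horizon <- trace$time_s <= horizon
  hit <- which(abs(kin$velocity) >= config$velocity_threshold_mps & in_horizon)
  if (length(hit) == 0L)
    return(list(verdict = "quasi-static", time_s = NA_real_,
                index = NA_integer_))
  list(verdict = "onset", time_s = trace$time_s[hit[1]], index = hit[1])
}

#' Segment a TUG trial from a radar range trace
#'
#' Locates the six transition points of the Timed Up and Go test on the
#' Kalman-filtered range: T0/T1 bound sit-to-stand (range first exceeding
#' D_pos, then reaching D_pos + d_qs), T2/T3 bound the turn (range reaching
#' and leaving D_pos + walkway length), T4 marks the return to the standing
#' position in front of the chair and T5 the completed sit. Thresholds use a
#' two-consecutive-sample persistence rule to reject single-sample noise.
#' T5 mirrors T0 geometrically (range back within `sit_tolerance_m` of the
#' chair); if the chair range is never re-reached, the fall-back is the
#' first point after T4 whose speed stays below the onset threshold for a
#' full onset window.
#'
#' @inheritParams detect_walk_onset
#' @return An object of class `tug_events`: list with `t0` ... `t5`
#'   (seconds) and `phases` (data.frame `label`, `start_s`, `end_s` tiling
#'   `[t0, t5]` with sit_to_stand, walk_forward, turn, walk_back,
#'   stand_to_sit).
#' @export
segment_tug <- function(trace, config = segmentation_config(), kf = NULL) {
  stopifnot(inherits(trace, "radar_trace"),
            inherits(config, "segmentation_config"))
  onset <- detect_walk_onset(trace, config, kf)
  if (onset$verdict == "quasi-static")
    stop("no activity: trace is quasi-static")
  kin <- trace_kinematics(trace, kf)
  d <- kin$position
  v <- kin$velocity
  tt <- trace$time_s
  n <- length(tt)
  dpos <- config$radar_offset_m
  d1 <- dpos + config$standing_offset_m
  d2 <- dpos + config$walk_distance_m

  # T0: first local point above D_pos, searched in the look-back window
  # before the onset (extended forward if the onset preceded the rise)
  lb_start <- which(tt >= onset$time_s - config$onset_window_s)[1]
  i0 <- first_sustained(d > dpos, lb_start)
  if (is.na(i0)) stop("incomplete trial: range never exceeds D_pos")

  i1 <- first_sustained(d >= d1, i0 + 1L)
  if (is.na(i1)) stop("incomplete trial: standing position never reached")

  i2 <- first_sustained(d >= d2, i1 + 1L)
  if (is.na(i2))
    stop("incomplete trial: range never reaches walk distance")

  # turn plateau: contiguous run around T2 staying within one range cell
  # of the walkway end; T3 is its last sample
  i3 <- i2
  while (i3 + 1L <= n && d[i3 + 1L] >= d2 - config$turn_tolerance_m)
    i3 <- i3 + 1L
  if (i3 >= n) stop("incomplete trial: walk back missing")

  i4 <- first_sustained(d <= d1, i3 + 1L)
  if (is.na(i4)) stop("incomplete trial: subject never returns to chair")

  i5 <- first_sustained(d <= dpos + config$sit_tolerance_m, i4 + 1L)
  if (is.na(i5)) {
    # fall back on a sustained-quiet velocity rule
    persist <- max(2L, ceiling(config$onset_window_s /
                                 attr(trace, "sample_interval_s")))
    i5 <- first_sustained(abs(v) < config$velocity_threshold_mps,
                          i4 + 1L, persist)
    if (is.na(i5)) stop("incomplete trial: stand-to-sit not found")
  }

  idx <- c(i0, i1, i2, i3, i4, i5)
  if (any(diff(idx) <= 0)) stop("segmentation failed: events out of order")
  tug_events(tt[i0], tt[i1], tt[i2], tt[i3], tt[i4], tt[i5])
}

#' TUG transition points and phase intervals
#'
#' @param t0,t1,t2,t3,t4,t5 Strictly increasing transition times (s).
#' @return An object of class `tug_events`.
#' @export
tug_events <- function(t0, t1, t2, t3, t4, t5) {
  ts <- c(t0, t1, t2, t3, t4, t5)
  stopifnot(all(is.finite(ts)), all(diff(ts) > 0))
  phases <- data.frame(
    label = c("sit_to_stand", "walk_forward", "turn", "walk_back",
              "stand_to_sit"),
    start_s = ts[1:5],
    end_s = ts[2:6])
  structure(list(t0 = t0, t1 = t1, t2 = t2, t3 = t3, t4 = t4, t5 = t5,
                 phases = phases),
            class = "tug_events")
}

#' @export
print.tug_events <- function(x, ...) {
  cat("TUG events (s):",
      sprintf("T%d=%.2f", 0:5, c(x$t0, x$t1, x$t2, x$t3, x$t4, x$t5)), "\n")
  print(x$phases)
  invisible(x)
}

#' Write TUG events to JSON
#'
#' @param events A [tug_events()].
#' @param path Output path.
#' @export
write_events_json <- function(events, path) {
  stopifnot(inherits(events, "tug_events"))
  obj <- list(t0 = events$t0, t1 = events$t1, t2 = events$t2,
              t3 = events$t3, t4 = events$t4, t5 = events$t5,
              phases = events$phases)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Per-stride length and speed from the radar range
#'
#' For each stride interval, stride length is the absolute range
#' displacement between the interval end points (sign-free so the rule
#' covers the walk back), and stride speed is length over duration. The
#' range is evaluated on the original trace by linear interpolation.
#'
#' @param trace A [radar_trace()].
#' @param stride_intervals List (or 2-column matrix) of `[start_s, end_s]`
#'   pairs inside the trace span with positive duration.
#' @return data.frame `start_s`, `end_s`, `length_m`, `speed_mps`.
#' @export
radar_stride_metrics <- function(trace, stride_intervals) {
  stopifnot(inherits(trace, "radar_trace"))
  if (is.matrix(stride_intervals))
    stride_intervals <- split(stride_intervals, row(stride_intervals)[, 1])
  span <- range(trace$time_s)
  # cubic endpoint evaluation: stride boundaries rarely sit on the radar
  # sample grid, and the range curves within a stride
  dfun <- stats::splinefun(trace$time_s, trace$distance_m, method = "fmm")
  out <- lapply(stride_intervals, function(iv) {
    iv <- as.numeric(iv)
    if (length(iv) != 2L || !all(is.finite(iv)))
      stop("stride interval must be a finite [start_s, end_s] pair")
    if (iv[2] <= iv[1]) stop("stride interval must have positive duration")
    if (iv[1] < span[1] || iv[2] > span[2])
      stop("stride interval outside trace span")
    dd <- dfun(iv)
    sl <- abs(dd[2] - dd[1])
    data.frame(start_s = iv[1], end_s = iv[2], length_m = sl,
               speed_mps = sl / (iv[2] - iv[1]))
  })
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Resample a radar trace by cubic interpolation
#'
#' Cubic-spline interpolation onto new time stamps, used to put the radar
#' stream on the insole clock. Source sample points are reproduced exactly.
#' Transition points should always be located on the original trace before
#' resampling.
#'
#' @param trace A [radar_trace()].
#' @param target_times Strictly increasing times within the source span.
#' @return A [radar_trace()] at `target_times`.
#' @export
resample_trace <- function(trace, target_times) {
  stopifnot(inherits(trace, "radar_trace"))
  target_times <- as.numeric(target_times)
  if (any(target_times < trace$time_s[1] |
          target_times > trace$time_s[nrow(trace)]))
    stop("extrapolation outside the source span is not supported")
  f <- stats::splinefun(trace$time_s, trace$distance_m, method = "fmm")
  radar_trace(target_times, pmax(0, f(target_times)))
}
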