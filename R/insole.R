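#' Instrumented-insole recording
#'
#' Time series from a single instrumented insole: anteroposterior (y-axis)
#' acceleration plus 2-4 force-sensitive-resistor channels, uniformly
#' sampled.
#'
#' @param time_s Time stamps in seconds (strictly increasing).
#' @param ay Anteroposterior acceleration (sensor units or g).
#' @param forces data.frame or matrix of 2-4 FSR channels, same length.
#' @return data.frame of class `insole_recording` with columns `time_s`,
#'   `ay`, `fsr1` ... `fsrN` and a `sample_rate_hz` attribute.
#' @export
insole_recording <- function(time_s, ay, forces) {
  time_s <- as.numeric(time_s)
  ay <- as.numeric(ay)
  forces <- as.data.frame(forces)
  nf <- ncol(forces)
  if (nf < 2L || nf > 4L) stop("need 2 to 4 force channels")
  stopifnot(length(time_s) == length(ay), nrow(forces) == length(ay),
            length(time_s) >= 2L, all(is.finite(time_s)),
            all(is.finite(ay)), all(vapply(forces, function(x)
              all(is.finite(x)), logical(1))))
  dt <- diff(time_s)
  if (any(dt <= 0)) stop("time_s must be strictly increasing")
  names(forces) <- paste0("fsr", seq_len(nf))
  df <- cbind(data.frame(time_s = time_s, ay = ay), forces)
  structure(df, sample_rate_hz = 1 / stats::median(dt),
            class = c("insole_recording", "data.frame"))
}

#' Read / write an insole recording CSV
#'
#' CSV with header `time_s,ay,fsr1,...,fsrN` (2-4 FSR columns).
#'
#' @param path File path.
#' @return `read_insole_csv` returns an [insole_recording()].
#' @export
read_insole_csv <- function(path) {
  df <- utils::read.csv(path)
  fcols <- grep("^fsr[0-9]+$", names(df), value = TRUE)
  if (!all(c("time_s", "ay") %in% names(df)) || length(fcols) < 2L)
    stop("insole CSV must have columns time_s,ay,fsr1..fsrN")
  insole_recording(df$time_s, df$ay, df[fcols])
}

#' @rdname read_insole_csv
#' @param rec An [insole_recording()].
#' @export
write_insole_csv <- function(rec, path) {
  stopifnot(inherits(rec, "insole_recording"))
  utils::write.csv(as.data.frame(rec), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Insole preprocessing settings
#'
#' @param median_window Median-filter width in samples (odd, >= 3).
#' @param butterworth_order Low-pass Butterworth order.
#' @param butterworth_cutoff_hz Cut-off frequency (below Nyquist).
#' @param max_stride_time_s Upper bound of the admissible inter-peak gap
#'   (Max_time).
#' @param peak_threshold_frac Optional fraction of the signal maximum below
#'   which candidate peaks are discarded; `NULL` (default) disables this
#'   pre-filter, detection being shape-based.
#' @param prominence_frac Shape-similarity criterion: a candidate peak is
#'   kept only if its smaller flank drop (min of PL, PR) reaches this
#'   fraction of the upper-decile flank drop over all candidates,
#'   separating true stride pulses from filter ripple and noise bumps.
#' @return Object of class `preprocess_config`.
#' @export
preprocess_config <- function(median_window = 5L,
                              butterworth_order = 2L,
                              butterworth_cutoff_hz = 3.0,
                              max_stride_time_s = 2.5,
                              peak_threshold_frac = NULL,
                              prominence_frac = 0.3) {
  median_window <- as.integer(median_window)
  if (median_window < 3L || median_window %% 2L == 0L)
    stop("median_window must be odd and >= 3")
  stopifnot(butterworth_order >= 1, butterworth_cutoff_hz > 0,
            max_stride_time_s > 0)
  if (!is.null(peak_threshold_frac))
    stopifnot(peak_threshold_frac > 0, peak_threshold_frac < 1)
  stopifnot(prominence_frac >= 0, prominence_frac < 1)
  structure(
    list(median_window = median_window,
         butterworth_order = as.integer(butterworth_order),
         butterworth_cutoff_hz = butterworth_cutoff_hz,
         max_stride_time_s = max_stride_time_s,
         peak_threshold_frac = peak_threshold_frac,
         prominence_frac = prominence_frac),
    class = "preprocess_config")
}

#' Normalize an insole recording
#'
#' Z-scores the acceleration (subtract mean, divide by population standard
#' deviation) and normalizes the total force (sum over the selected FSR
#' channels) by its maximum. The raw acceleration should be kept for
#' stride-length estimation; the normalized copy drives segmentation.
#'
#' @param rec An [insole_recording()].
#' @param force_subset Integer indices of the FSR channels to sum
#'   (default: all), supporting the 4 -> 3 -> 2 sensor-reduction study.
#' @return List of class `insole_norm`: `time_s`, `ay` (normalized),
#'   `total_force` (max 1), `sample_rate_hz`, `force_subset`.
#' @export
normalize_recording <- function(rec, force_subset = NULL) {
  stopifnot(inherits(rec, "insole_recording"))
  fcols <- grep("^fsr[0-9]+$", names(rec), value = TRUE)
  if (is.null(force_subset)) force_subset <- seq_along(fcols)
  force_subset <- as.integer(force_subset)
  if (any(force_subset < 1L | force_subset > length(fcols)))
    stop("force_subset out of range")
  ay <- rec$ay
  n <- length(ay)
  sd_pop <- sqrt(sum((ay - mean(ay))^2) / n)
  if (sd_pop == 0) stop("constant acceleration signal cannot be normalized")
  total <- rowSums(as.data.frame(rec)[fcols[force_subset]])
  if (max(total) <= 0) stop("total force has no positive maximum")
  structure(
    list(time_s = rec$time_s,
         ay = (ay - mean(ay)) / sd_pop,
         total_force = unname(total / max(total)),
         sample_rate_hz = attr(rec, "sample_rate_hz"),
         force_subset = force_subset),
    class = "insole_norm")
}

#' Low-pass filter the acceleration signal
#'
#' Applies a median filter (impulse rejection) followed by a zero-phase
#' Butterworth low-pass (forward-backward), preserving the DC level and
#' peak timing.
#'
#' @param ay Acceleration series.
#' @param fs Sample rate in Hz.
#' @param config A [preprocess_config()].
#' @return Filtered series, same length.
#' @export
lowpass_ay <- function(ay, fs, config = preprocess_config()) {
  stopifnot(inherits(config, "preprocess_config"), fs > 0)
  ay <- as.numeric(ay)
  if (length(ay) <= 3L * config$median_window)
    stop("signal too short for the median window")
  if (config$butterworth_cutoff_hz >= fs / 2)
    stop("Butterworth cutoff must be below the Nyquist frequency")
  med <- stats::runmed(ay, config$median_window, endrule = "median")
  bf <- signal::butter(config$butterworth_order,
                       config$butterworth_cutoff_hz / (fs / 2),
                       type = "low")
  # odd-reflection padding suppresses the start/end transients of the
  # forward-backward pass
  n <- length(med)
  np <- min(n - 1L, as.integer(ceiling(3 * fs / config$butterworth_cutoff_hz)))
  left <- 2 * med[1] - med[(np + 1L):2L]
  right <- 2 * med[n] - med[(n - 1L):(n - np)]
  y <- as.numeric(signal::filtfilt(bf, c(left, med, right)))
  y[(np + 1L):(np + n)]
}

#' Zero crossings and locking period
#'
#' Finds the sign changes of the filtered acceleration and sets the
#' locking period (lockP) to the mean interval between consecutive
#' crossings. lockP is the moving-window length of the stride-peak
#' detector and the lower bound of the admissible inter-peak gap.
#'
#' @param ay_filtered Filtered (normalized) acceleration series.
#' @param fs Sample rate in Hz.
#' @return List with `zero_crossings` (indices of the sample preceding
#'   each crossing) and `lockp_s` (seconds).
#' @export
locking_period <- function(ay_filtered, fs) {
  stopifnot(fs > 0)
  x <- as.numeric(ay_filtered)
  cross <- which(x[-length(x)] * x[-1] < 0)
  if (length(cross) < 2L) stop("fewer than 2 zero crossings")
  list(zero_crossings = cross,
       lockp_s = mean(diff(cross)) / fs)
}

# parabolic refinement of a peak time (3-point fit on the sample grid)
refine_peak_time <- function(x, i, fs) {
  if (i <= 1L || i >= length(x)) return((i - 1) / fs)
  denom <- x[i - 1L] - 2 * x[i] + x[i + 1L]
  delta <- if (denom >= 0) 0 else 0.5 * (x[i - 1L] - x[i + 1L]) / denom
  (i - 1 + max(-0.5, min(0.5, delta))) / fs
}

# one application of the inter-peak gap rule (Eq. 2 analogue):
# a peak too close to the previously retained peak is dropped; a peak
# whose gap to the NEXT retained peak exceeds max_gap is dropped
apply_gap_rule <- function(times, valid, lockp_s, max_gap_s) {
  idx <- which(valid)
  if (length(idx) >= 2L) {
    keep_ref <- times[idx[1]]
    for (j in idx[-1]) {
      if (times[j] - keep_ref < lockp_s) valid[j] <- FALSE
      else keep_ref <- times[j]
    }
  }
  idx <- which(valid)
  if (length(idx) >= 2L) {
    gaps <- diff(times[idx])
    valid[idx[which(gaps > max_gap_s)]] <- FALSE
  }
  valid
}

#' Detect stride peaks with the locking-period algorithm
#'
#' Slides a window of length lockP over the filtered acceleration, takes
#' the per-window maximum as a candidate peak, then re-centers a
#' lockP-sized window on each candidate and relocates it to the local
#' maximum until stable (merging duplicates). Only positive excursions
#' qualify (the signal is zero-mean after normalization). For each peak,
#' PL and PR are the drops from the peak to the minima immediately before
#' (toe-off) and after (heel-strike) inside the centered window. A peak is
#' invalidated when its gap to the neighboring retained peak leaves the
#' admissible range `[lockP, max_stride_time_s]`; the rule is iterated to
#' a fixed point so re-validating a validated set changes nothing. The
#' stride count is the number of valid peaks minus one.
#'
#' @param ay_filtered Filtered normalized acceleration series.
#' @param fs Sample rate (Hz).
#' @param lockp_s Locking period in seconds (from [locking_period()]).
#' @param config A [preprocess_config()].
#' @return Object of class `stride_events`: `peaks` data.frame (`index`,
#'   `time_s` sub-sample refined, `value`, `pl`, `pr`, `valid`),
#'   `stride_boundaries` data.frame (`start_s`, `end_s`), `n_strides`,
#'   `lockp_s`.
#' @export
detect_stride_peaks <- function(ay_filtered, fs, lockp_s,
                                config = preprocess_config()) {
  stopifnot(inherits(config, "preprocess_config"), fs > 0, lockp_s > 0)
  x <- as.numeric(ay_filtered)
  n <- length(x)
  if (n == 0L) stop("empty signal")
  L <- as.integer(round(lockp_s * fs))
  if (L < 2L) stop("locking period shorter than 2 samples")
  half <- L %/% 2L

  # tile the record with lockP windows, one candidate max per window
  starts <- seq(1L, n, by = L)
  cand <- vapply(starts, function(s) {
    e <- min(n, s + L - 1L)
    s - 1L + which.max(x[s:e])
  }, integer(1))
  cand <- unique(cand)

  # iterative re-centering onto local maxima at the lockP scale
  repeat {
    moved <- vapply(cand, function(i) {
      s <- max(1L, i - half); e <- min(n, i + half)
      s - 1L + which.max(x[s:e])
    }, integer(1))
    moved <- sort(unique(moved))
    if (identical(moved, sort(unique(cand)))) break
    cand <- moved
  }
  cand <- cand[x[cand] > 0]  # a stride peak is a positive excursion
  if (!is.null(config$peak_threshold_frac) && length(cand))
    cand <- cand[x[cand] >= config$peak_threshold_frac * max(x)]

  if (length(cand) == 0L) {
    return(structure(list(
      peaks = data.frame(index = integer(), time_s = numeric(),
                         value = numeric(), pl = numeric(), pr = numeric(),
                         valid = logical()),
      stride_boundaries = data.frame(start_s = numeric(),
                                     end_s = numeric()),
      n_strides = 0L, lockp_s = lockp_s), class = "stride_events"))
  }

  pl <- pr <- numeric(length(cand))
  for (j in seq_along(cand)) {
    i <- cand[j]
    s <- max(1L, i - half); e <- min(n, i + half)
    pl[j] <- x[i] - min(x[s:i])   # peak minus val(TO)
    pr[j] <- x[i] - min(x[i:e])   # peak minus val(HS)
  }
  tms <- vapply(cand, function(i) refine_peak_time(x, i, fs), numeric(1))

  # shape-similarity correction: drop ripple bumps whose flank drops are
  # far below those of the bulk of the candidates
  valid <- rep(TRUE, length(cand))
  if (config$prominence_frac > 0 && length(cand) >= 2L) {
    prom <- pmin(pl, pr)
    ref <- stats::quantile(prom, 0.9, names = FALSE)
    valid <- prom >= config$prominence_frac * ref
  }
  repeat {
    new_valid <- apply_gap_rule(tms, valid, lockp_s,
                                config$max_stride_time_s)
    if (identical(new_valid, valid)) break
    valid <- new_valid
  }

  vt <- tms[valid]
  boundaries <- if (length(vt) >= 2L)
    data.frame(start_s = vt[-length(vt)], end_s = vt[-1])
  else data.frame(start_s = numeric(), end_s = numeric())

  structure(list(
    peaks = data.frame(index = cand, time_s = tms, value = x[cand],
                       pl = pl, pr = pr, valid = valid),
    stride_boundaries = boundaries,
    n_strides = max(0L, sum(valid) - 1L),
    lockp_s = lockp_s), class = "stride_events")
}

#' @export
print.stride_events <- function(x, ...) {
  cat(sprintf("stride_events: %d candidate peaks, %d valid, %d strides, lockP = %.3f s\n",
              nrow(x$peaks), sum(x$peaks$valid), x$n_strides, x$lockp_s))
  invisible(x)
}

#' Validate acceleration stride count against the force signal
#'
#' Counts swing excursions of the normalized total force (drops below a
#' low level bounded by the high stance level on both sides, with
#' hysteresis) and compares the count with the number of valid
#' acceleration peaks.
#'
#' @param total_force Normalized total force (max 1).
#' @param events A `stride_events` object from [detect_stride_peaks()].
#' @param fs Sample rate (Hz).
#' @param high,low Hysteresis levels as fractions of the maximum.
#' @return List: `force_cycles`, `accel_peaks`, `agreement`,
#'   `discrepancy`.
#' @export
validate_with_force <- function(total_force, events, fs,
                                high = 0.6, low = 0.2) {
  stopifnot(inherits(events, "stride_events"))
  f <- as.numeric(total_force)
  if (abs(max(f) - 1) > 0.05)
    stop("total force must be normalized to maximum 1")
  state <- "unknown"
  cycles <- 0L
  pending_low <- FALSE
  for (v in f) {
    if (v >= high) {
      if (pending_low) { cycles <- cycles + 1L; pending_low <- FALSE }
      state <- "high"
    } else if (v <= low && state == "high") {
      state <- "low"; pending_low <- TRUE
    }
  }
  np <- sum(events$peaks$valid)
  list(force_cycles = cycles, accel_peaks = np,
       agreement = cycles == np, discrepancy = abs(cycles - np))
}

#' Stride times from the force signal alone
#'
#' Detects the swing-onset edges of the normalized total force (downward
#' crossings of a mid level after a stance, hysteresis against chatter,
#' crossing times linearly interpolated) and returns the intervals between
#' consecutive edges. Used for the sensor-reduction comparison of
#' force-derived versus acceleration-derived stride times.
#'
#' @param total_force Normalized total force (max 1).
#' @param fs Sample rate (Hz).
#' @param high Stance level re-arming the detector.
#' @param mid Falling-edge crossing level.
#' @return Numeric vector of stride times (s).
#' @export
force_stride_times <- function(total_force, fs, high = 0.6, mid = 0.4) {
  f <- as.numeric(total_force)
  if (abs(max(f) - 1) > 0.05)
    stop("total force must be normalized to maximum 1")
  armed <- FALSE
  edges <- numeric(0)
  pending <- NA_real_
  pending_i <- NA_integer_
  max_swing <- round(0.8 * fs)  # a swing unload must re-arm quickly
  for (i in seq_along(f)) {
    if (f[i] >= high) {
      if (!is.na(pending)) { edges <- c(edges, pending); pending <- NA_real_ }
      armed <- TRUE
    } else if (armed && f[i] < mid) {
      frac <- (f[i - 1L] - mid) / (f[i - 1L] - f[i])
      pending <- (i - 2L + frac) / fs
      pending_i <- i
      armed <- FALSE
    }
    if (!is.na(pending) && i - pending_i > max_swing) pending <- NA_real_
  }
  if (length(edges) < 2L) return(numeric(0))
  diff(edges)
}

#' Detect sit-to-stand and stand-to-sit from the force signal
#'
#' Sit-to-stand is the first sustained rise of the normalized total force
#' from the low seated plateau to the first attainment of the standing
#' level; stand-to-sit is the final decline from the standing level back
#' to the ending seated plateau.
#'
#' @param total_force Normalized total force (max 1).
#' @param fs Sample rate (Hz).
#' @param standing_frac Fraction of the maximum taken as the standing
#'   level.
#' @param plateau_margin Allowed excursion above the seated plateau when
#'   locating the start/end of the transitions.
#' @param min_plateau_s Minimum duration of a low period for it to count
#'   as a seated plateau rather than a brief swing unload.
#' @return List with `sit_to_stand` and `stand_to_sit`, each
#'   `c(start_s, end_s)`.
#' @export
detect_sts_phases <- function(total_force, fs, standing_frac = 0.95,
                              plateau_margin = 0.05, min_plateau_s = 1.0) {
  f <- as.numeric(total_force)
  n <- length(f)
  if (abs(max(f) - 1) > 0.05)
    stop("total force must be normalized to maximum 1")
  w <- max(2L, round(fs))  # one-second plateau estimate
  base0 <- stats::median(f[seq_len(min(w, n))])
  base1 <- stats::median(f[seq(max(1L, n - w + 1L), n)])

  # sustained low periods (seated plateaus, not brief swing unloads);
  # noise blips shorter than 0.2 s do not break a plateau
  low_runs <- function(base) {
    mask <- f <= base + plateau_margin
    r <- rle(mask)
    if (length(r$lengths) > 2L) {
      interior <- 2:(length(r$lengths) - 1L)
      close_gap <- !r$values[interior] &
        r$lengths[interior] <= round(0.2 * fs)
      r$values[interior][close_gap] <- TRUE
      mask <- inverse.rle(r)
      r <- rle(mask)
    }
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- r$values & r$lengths >= round(min_plateau_s * fs)
    cbind(start = starts[keep], end = ends[keep])
  }

  i_end <- which(f >= standing_frac)[1]
  if (is.na(i_end) || base0 >= standing_frac - plateau_margin)
    stop("no sit-to-stand rise found")
  runs0 <- low_runs(base0)
  before <- runs0[runs0[, "end"] < i_end, , drop = FALSE]
  i_start <- if (nrow(before)) before[nrow(before), "end"] else 1L
  s2st <- c(i_start - 1L, i_end - 1L) / fs

  j_start <- max(which(f >= standing_frac))
  runs1 <- low_runs(base1)
  after <- runs1[runs1[, "start"] > j_start, , drop = FALSE]
  if (j_start >= n || base1 >= standing_frac - plateau_margin ||
      nrow(after) == 0L)
    stop("no stand-to-sit decline found")
  j_end <- after[1L, "start"]
  st2s <- c(j_start - 1L, j_end - 1L) / fs
  list(sit_to_stand = s2st, stand_to_sit = st2s)
}

#' Per-stride gait parameters
#'
#' Stride time is the duration of each stride boundary; cadence is
#' 60 x steps-per-stride / stride time (steps per minute); stride speed is
#' stride length over stride time.
#'
#' @param events A `stride_events` object, or a data.frame with `start_s`
#'   and `end_s` columns.
#' @param stride_lengths Stride lengths in meters, one per stride.
#' @param steps_per_stride Steps per stride (2 for typical gait).
#' @return data.frame `stride_time_s`, `cadence_spm`, `stride_length_m`,
#'   `stride_speed_mps`.
#' @export
compute_gait_parameters <- function(events, stride_lengths,
                                    steps_per_stride = 2) {
  b <- if (inherits(events, "stride_events")) events$stride_boundaries
       else as.data.frame(events)
  stopifnot(all(c("start_s", "end_s") %in% names(b)))
  if (nrow(b) != length(stride_lengths))
    stop("stride_lengths must match the number of strides")
  st <- b$end_s - b$start_s
  if (any(st <= 0)) stop("stride times must be positive")
  data.frame(stride_time_s = st,
             cadence_spm = 60 * steps_per_stride / st,
             stride_length_m = as.numeric(stride_lengths),
             stride_speed_mps = as.numeric(stride_lengths) / st)
}
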