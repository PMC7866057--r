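#' Simulation parameters for a synthetic TUG trial
#'
#' Defines the geometry and gait of a simulated Timed Up and Go trial:
#' sit at the chair, rise by d_qs, walk the 3 m walkway, turn 180 degrees,
#' walk back and sit down, observed simultaneously by a range-only radar
#' placed `radar_offset_m` behind the chair and by a single instrumented
#' insole. Defaults describe a healthy adult at comfortable pace: 1.3 m
#' strides of 1.1 s, a turn taken at half the straight-line speed (one
#' full gait cycle of twice the stride time), a 5 Hz radar and a 100 Hz
#' insole.
#'
#' @param radar_offset_m Radar-to-chair distance D_pos (m).
#' @param standing_offset_m Chair-to-standing distance d_qs (m).
#' @param walk_distance_m Walkway length (m).
#' @param sit_back_m Range offset of the seated torso behind the chair
#'   reference point (m).
#' @param sit_duration_s,end_sit_duration_s Seated spans before/after.
#' @param s2st_duration_s,st2s_duration_s Sit-to-stand / stand-to-sit
#'   durations (s).
#' @param turn_duration_s Turn duration; one full gait cycle (s).
#' @param stride_length_m,stride_length_sd_m Mean/SD of stride length (m).
#' @param stride_time_s,stride_time_sd_s Mean/SD of stride time (s).
#' @param radar_rate_hz,insole_rate_hz Sampling rates.
#' @param radar_noise_sd_m Radar range jitter SD (m).
#' @param ay_noise_sd Accelerometer noise SD (sensor units).
#' @param force_noise_sd FSR noise SD (fraction of body-weight force).
#' @param n_fsr Number of FSR channels (2-4).
#' @param seed Optional RNG seed for reproducibility.
#' @return Object of class `sim_params`.
#' @export
sim_params <- function(radar_offset_m = 0.5,
                       standing_offset_m = 0.3,
                       walk_distance_m = 3.0,
                       sit_back_m = 0.1,
                       sit_duration_s = 5.0,
                       end_sit_duration_s = 5.0,
                       s2st_duration_s = 1.0,
                       st2s_duration_s = 1.0,
                       turn_duration_s = 2.2,
                       stride_length_m = 1.3,
                       stride_length_sd_m = 0.05,
                       stride_time_s = 1.1,
                       stride_time_sd_s = 0.05,
                       radar_rate_hz = 5,
                       insole_rate_hz = 100,
                       radar_noise_sd_m = 0.02,
                       ay_noise_sd = 0.05,
                       force_noise_sd = 0.01,
                       n_fsr = 3L,
                       seed = NULL) {
  p <- as.list(environment())
  durs <- c(sit_duration_s, end_sit_duration_s, s2st_duration_s,
            st2s_duration_s, turn_duration_s, stride_length_m,
            stride_time_s, radar_rate_hz, insole_rate_hz,
            radar_offset_m, standing_offset_m, walk_distance_m)
  stopifnot(all(is.finite(durs)), all(durs > 0),
            radar_noise_sd_m >= 0, ay_noise_sd >= 0, force_noise_sd >= 0,
            stride_length_sd_m >= 0, stride_time_sd_s >= 0,
            n_fsr >= 2L, n_fsr <= 4L)
  if (walk_distance_m <= standing_offset_m)
    stop("walkway must be longer than the standing offset")
  if (stride_length_m > walk_distance_m)
    stop("infeasible geometry: stride longer than the walkway")
  structure(p, class = "sim_params")
}

# intra-stride advance profile: unit displacement with gait-like speed
# modulation, s(0)=0, s(1)=1, ds/dtau in [0.92, 1.08]
stride_profile <- function(tau) {
  tau - 0.08 * sin(2 * pi * tau) / (2 * pi)
}

# amplitude of the anteroposterior pulse producing a given stride length
# under the fourth-root (hip-bounce) relation with the default K
ay_amp_for_sl <- function(sl, k = 0.9763, hs_depth = 0.45) {
  (sl / k)^4 / (1 + hs_depth)
}

#' Simulate a complete TUG trial
#'
#' Generates the paired radar range trace and insole recording of one TUG
#' trial together with its ground truth. The radar sees the line-of-sight
#' range: a jittered seated plateau, a brisk-then-easing sit-to-stand rise
#' of d_qs (plus the seated set-back), stride-wise advance to the end of
#' the walkway, a turn plateau with a small overshoot oscillation, the
#' mirrored walk back and an easing-then-dropping stand-to-sit descent.
#' The insole sees one raised-cosine acceleration pulse per stride
#' boundary flanked by a toe-off minimum before and a deeper heel-strike
#' minimum after, with FSR channels high in stance, near zero in swing and
#' at a low plateau while seated. Pulse amplitude follows the fourth-power
#' stride-length relation so faster, longer strides shake the foot harder.
#'
#' @param params A [sim_params()].
#' @return List with `radar` ([radar_trace()]), `insole`
#'   ([insole_recording()]) and `truth` (event times `t0`...`t5`, per-stride
#'   boundaries/lengths/times/labels, heel-strike and toe-off times, pulse
#'   times).
#' @export
#' @examples
#' trial <- simulate_tug(sim_params(seed = 42))
#' trial$truth$n_strides
simulate_tug <- function(params = sim_params()) {
  stopifnot(inherits(params, "sim_params"))
  p <- params
  if (!is.null(p$seed)) set.seed(p$seed)

  advance <- p$walk_distance_m - p$standing_offset_m
  overshoot <- 0.04
  n_walk <- as.integer(max(1, round(advance / p$stride_length_m)))

  draw_strides <- function(n, total) {
    len <- if (p$stride_length_sd_m > 0)
      pmax(0.3 * p$stride_length_m,
           stats::rnorm(n, p$stride_length_m, p$stride_length_sd_m))
    else rep(p$stride_length_m, n)
    len <- len * total / sum(len)
    st <- if (p$stride_time_sd_s > 0)
      pmax(0.4 * p$stride_time_s,
           stats::rnorm(n, p$stride_time_s, p$stride_time_sd_s))
    else rep(p$stride_time_s, n)
    list(len = len, st = st)
  }
  wf <- draw_strides(n_walk, advance + overshoot)
  wb <- draw_strides(n_walk, advance + overshoot)

  t0 <- p$sit_duration_s
  t1 <- t0 + p$s2st_duration_s
  t2 <- t1 + sum(wf$st)
  t3 <- t2 + p$turn_duration_s
  t4 <- t3 + sum(wb$st)
  t5 <- t4 + p$st2s_duration_s
  t_end <- t5 + p$end_sit_duration_s

  stride_st <- c(wf$st, p$turn_duration_s, wb$st)
  stride_sl <- c(wf$len, p$stride_length_m, wb$len)
  labels <- c(rep("walk_forward", n_walk), "turn", rep("walk_back", n_walk))
  bounds <- t1 + cumsum(c(0, stride_st))  # pulse times b_0 ... b_m
  m <- length(stride_st)

  d_sit <- p$radar_offset_m - p$sit_back_m
  d_stand <- p$radar_offset_m + p$standing_offset_m
  d_far <- d_stand + advance + overshoot
  rise <- p$sit_back_m + p$standing_offset_m
  wf_pos <- d_stand + cumsum(c(0, wf$len))
  wb_pos <- d_far - cumsum(c(0, wb$len))

  range_at <- function(t) {
    if (t < t0) return(d_sit)
    if (t < t1) return(d_sit + rise * sin(pi / 2 * (t - t0) / (t1 - t0)))
    if (t < t2) {
      i <- findInterval(t, bounds[1:(n_walk + 1L)],
                        rightmost.closed = TRUE)
      i <- min(i, n_walk)
      tau <- (t - bounds[i]) / wf$st[i]
      return(wf_pos[i] + wf$len[i] * stride_profile(tau))
    }
    if (t < t3) {
      tau <- (t - t2) / p$turn_duration_s
      return(d_far + 0.015 * sin(2 * pi * tau) * sin(pi * tau))
    }
    if (t < t4) {
      wb_b <- bounds[(n_walk + 2L):(m + 1L)]
      i <- findInterval(t, wb_b, rightmost.closed = TRUE)
      i <- max(1L, min(i, n_walk))
      tau <- (t - wb_b[i]) / wb$st[i]
      return(wb_pos[i] - wb$len[i] * stride_profile(tau))
    }
    if (t < t5)
      return(d_stand - rise * (1 - cos(pi / 2 * (t - t4) / (t5 - t4))))
    d_sit
  }

  rt <- seq(0, t_end, by = 1 / p$radar_rate_hz)
  rd <- vapply(rt, range_at, numeric(1))
  if (p$radar_noise_sd_m > 0)
    rd <- rd + stats::rnorm(length(rd), 0, p$radar_noise_sd_m)
  radar <- radar_trace(rt, pmax(0, rd))

  # ---- insole ----------------------------------------------------------
  it <- seq(0, t_end, by = 1 / p$insole_rate_hz)
  ni <- length(it)
  ay <- numeric(ni)
  # per-pulse amplitude from the mean length of the adjacent strides
  sl_at_pulse <- vapply(seq_len(m + 1L), function(j) {
    adj <- c(if (j > 1L) stride_sl[j - 1L], if (j <= m) stride_sl[j])
    mean(adj)
  }, numeric(1))
  amp <- ay_amp_for_sl(sl_at_pulse)
  st_at_pulse <- vapply(seq_len(m + 1L), function(j) {
    adj <- c(if (j > 1L) stride_st[j - 1L], if (j <= m) stride_st[j])
    min(adj)
  }, numeric(1))
  width <- 0.18 * st_at_pulse
  dip_hw <- 0.15
  dip_off <- width + dip_hw
  add_bump <- function(sig, center, half_width, height) {
    idx <- which(abs(it - center) <= half_width)
    sig[idx] <- sig[idx] + height / 2 *
      (1 + cos(pi * (it[idx] - center) / half_width))
    sig
  }
  for (j in seq_len(m + 1L)) {
    ay <- add_bump(ay, bounds[j], width[j], amp[j])
    ay <- add_bump(ay, bounds[j] - dip_off[j], dip_hw, -0.25 * amp[j])  # TO
    ay <- add_bump(ay, bounds[j] + dip_off[j], dip_hw, -0.45 * amp[j])  # HS
  }
  if (p$ay_noise_sd > 0) ay <- ay + stats::rnorm(ni, 0, p$ay_noise_sd)

  # total-force envelope: seated plateau, linear rise/fall, stance level 1;
  # weight-bearing completes slightly before the first step and starts to
  # unload slightly after the last, so the swing transitions ride on a
  # full-weight base
  lead <- 0.15
  r_up <- c(t0, max(t0 + 0.5 * (t1 - t0), t1 - lead))
  r_dn <- c(min(t4 + lead, t4 + 0.5 * (t5 - t4)), t5)
  base <- rep(0.25, ni)
  iu <- it >= r_up[1] & it < r_up[2]
  base[iu] <- 0.25 + 0.75 * (it[iu] - r_up[1]) / (r_up[2] - r_up[1])
  base[it >= r_up[2] & it < r_dn[1]] <- 1
  id <- it >= r_dn[1] & it < r_dn[2]
  base[id] <- 1 - 0.75 * (it[id] - r_dn[1]) / (r_dn[2] - r_dn[1])
  gate <- rep(1, ni)
  swing_half <- 0.15
  trans <- 0.06
  for (j in seq_len(m + 1L)) {
    u <- abs(it - bounds[j])
    lowz <- u <= swing_half - trans / 2
    edge <- u > swing_half - trans / 2 & u < swing_half + trans / 2
    g <- rep(1, ni)
    g[lowz] <- 0.05
    g[edge] <- 0.05 + 0.95 *
      (1 - cos(pi * (u[edge] - swing_half + trans / 2) / trans)) / 2
    gate <- pmin(gate, g)
  }
  total <- base * gate
  shares <- list(NULL, c(0.55, 0.45), c(0.45, 0.35, 0.20),
                 c(0.35, 0.30, 0.20, 0.15))[[p$n_fsr]]
  forces <- vapply(shares, function(s) {
    f <- s * total
    if (p$force_noise_sd > 0)
      f <- pmax(0, f + stats::rnorm(ni, 0, p$force_noise_sd))
    f
  }, numeric(ni))
  insole <- insole_recording(it, ay, forces)

  truth <- list(
    t0 = t0, t1 = t1, t2 = t2, t3 = t3, t4 = t4, t5 = t5,
    strides = data.frame(
      start_s = bounds[seq_len(m)],
      end_s = bounds[seq_len(m) + 1L],
      stride_length_m = stride_sl,
      stride_time_s = stride_st,
      label = labels),
    pulse_times_s = bounds,
    toe_off_s = bounds - dip_off,
    heel_strike_s = bounds + dip_off,
    n_strides = m,
    n_walk_forward = n_walk,
    n_walk_back = n_walk,
    params = p)
  list(radar = radar, insole = insole, truth = truth)
}

#' Simulate a quasi-static radar trace
#'
#' Jittered constant range, emulating a subject sitting (or standing)
#' still in front of the radar; for jitter SDs up to ~0.02 m the filtered
#' velocity stays below the walking-onset threshold by construction.
#'
#' @param duration_s Positive duration (s).
#' @param range_m Constant range (m).
#' @param jitter_sd_m Range jitter SD (m).
#' @param rate_hz Radar frame rate (Hz).
#' @param seed Optional RNG seed.
#' @return A [radar_trace()].
#' @export
simulate_quasi_static <- function(duration_s, range_m = 0.4,
                                  jitter_sd_m = 0.01, rate_hz = 5,
                                  seed = NULL) {
  if (!is.finite(duration_s) || duration_s <= 0)
    stop("duration must be positive")
  if (!is.null(seed)) set.seed(seed)
  tt <- seq(0, duration_s, by = 1 / rate_hz)
  d <- rep(range_m, length(tt))
  if (jitter_sd_m > 0) d <- d + stats::rnorm(length(tt), 0, jitter_sd_m)
  radar_trace(tt, pmax(0, d))
}

#' Write a simulated trial to disk
#'
#' Writes `<prefix>_radar.csv`, `<prefix>_insole.csv` and
#' `<prefix>_truth.json`.
#'
#' @param trial Result of [simulate_tug()].
#' @param prefix Output path prefix.
#' @return The three paths, invisibly.
#' @export
write_trial <- function(trial, prefix) {
  paths <- paste0(prefix, c("_radar.csv", "_insole.csv", "_truth.json"))
  write_radar_csv(trial$radar, paths[1])
  write_insole_csv(trial$insole, paths[2])
  tr <- trial$truth
  tr$params <- tr$params[setdiff(names(tr$params), "seed")]
  jsonlite::write_json(tr, paths[3], auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(paths)
}
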