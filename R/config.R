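#' Default analysis configuration
#'
#' Nested list of all tunable settings, grouped per processing stage:
#'
#' * `kf`: `ts_s` (tracking update, s), `r` (measurement-noise variance,
#'   m^2), `q0_diag` (process-noise diagonal).
#' * `segmentation`: `radar_offset_m` (D_pos, radar-to-chair distance),
#'   `walk_distance_m` (TUG walkway), `standing_offset_m` (d_qs, chair-to-
#'   standing-position distance), `velocity_threshold_mps` (walking-onset
#'   threshold), `onset_window_s` (accumulation window), and
#'   `quasi_static_timeout_s` (how long to wait before declaring the trace
#'   quasi-static), plus `turn_tolerance_m` (range tolerance when locating
#'   the end of the turn plateau) and `sit_tolerance_m` (range tolerance
#'   when locating the end of stand-to-sit).
#' * `preprocess`: insole filtering (`median_window`, `butterworth_order`,
#'   `butterworth_cutoff_hz`), `max_stride_time_s` (upper bound of the
#'   admissible inter-peak gap) and `peak_threshold_frac` (optional
#'   amplitude pre-filter, disabled by default).
#' * `calibration`: `k1` (unit conversion of the mean-absolute estimator)
#'   and `k` (base calibration coefficient; the Weinberg estimator uses K,
#'   the Scarlett estimator 2K).
#' * `rofa`: `aggregate` ("per_stride" scores each stride then averages, or
#'   "trial_mean" scores the trial-mean parameter) and `steps_per_stride`.
#'
#' @return Nested configuration list.
#' @export
tug_config <- function() {
  list(
    kf = list(ts_s = 0.2, r = 0.04, q0_diag = c(0.04, 0.01, 0.01)),
    segmentation = list(
      radar_offset_m = 0.5,
      walk_distance_m = 3.0,
      standing_offset_m = 0.3,
      velocity_threshold_mps = 0.4,
      onset_window_s = 3.0,
      quasi_static_timeout_s = 30.0,
      turn_tolerance_m = 0.1,
      sit_tolerance_m = 0.03),
    preprocess = list(
      median_window = 5L,
      butterworth_order = 2L,
      butterworth_cutoff_hz = 3.0,
      max_stride_time_s = 2.5,
      peak_threshold_frac = NULL,
      prominence_frac = 0.3),
    calibration = list(k1 = 0.98, k = 0.9763),
    rofa = list(aggregate = "per_stride", steps_per_stride = 2)
  )
}

# recursively overlay user values onto defaults
merge_config <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(base[[nm]]) && is.list(override[[nm]])) {
      base[[nm]] <- merge_config(base[[nm]], override[[nm]])
    } else {
      base[[nm]] <- override[[nm]]
    }
  }
  base
}

#' Read a JSON configuration file
#'
#' Reads a nested JSON configuration and overlays it onto [tug_config()]
#' defaults, so a file only needs to state the settings it changes.
#'
#' @param path Path to a JSON file, or `NULL` for pure defaults.
#' @return Nested configuration list.
#' @export
read_config <- function(path = NULL) {
  cfg <- tug_config()
  if (is.null(path)) return(cfg)
  if (!file.exists(path)) stop("config file not found: ", path)
  user <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  merge_config(cfg, user)
}

# build the module-level config objects out of the nested list
kf_config_of <- function(cfg) {
  filter_config(sample_interval_s = cfg$kf$ts_s,
                measurement_noise = cfg$kf$r,
                process_noise_init = cfg$kf$q0_diag)
}
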