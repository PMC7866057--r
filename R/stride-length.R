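#' Calibration constants for the stride-length estimators
#'
#' K1 is the unit-conversion constant of the mean-absolute-acceleration
#' estimator (default 0.98). K is the single free calibration coefficient
#' obtained as the mean ratio of estimated to real distances (default
#' 0.9763); the Weinberg estimator uses K2 = K and the Scarlett estimator
#' K3 = 2K, maintained as a linked constraint.
#'
#' @param k1 Unit-conversion constant of the first estimator.
#' @param k Base calibration coefficient.
#' @return Object of class `calibration_constants` with fields `k1`, `k`,
#'   `k2` (= k) and `k3` (= 2 k).
#' @export
calibration_constants <- function(k1 = 0.98, k = 0.9763) {
  stopifnot(is.finite(k1), k1 > 0, is.finite(k), k > 0)
  structure(list(k1 = k1, k = k, k2 = k, k3 = 2 * k),
            class = "calibration_constants")
}

check_window <- function(ay, min_n = 1L) {
  ay <- as.numeric(ay)
  if (length(ay) < min_n) stop("stride window too short")
  if (any(!is.finite(ay))) stop("stride window must be finite")
  ay
}

#' Stride length from the mean absolute acceleration
#'
#' First estimator: SL = K1 * (mean |Ay_i|)^(1/3), the empirical
#' cube-root relation between average anteroposterior acceleration over a
#' stride and stride length. Acceleration enters in raw sensor units (the
#' z-scored copy used for segmentation destroys the amplitude information
#' the estimator needs).
#'
#' @param ay Acceleration samples over one stride (raw units).
#' @param k1 Unit-conversion constant.
#' @return Stride length in meters.
#' @export
#' @examples
#' sl_mean_abs(rep(1, 4))  # 0.98
sl_mean_abs <- function(ay, k1 = 0.98) {
  ay <- check_window(ay, 1L)
  stopifnot(k1 > 0)
  k1 * (mean(abs(ay)))^(1 / 3)
}

#' Stride length from the acceleration range (Weinberg)
#'
#' Second estimator: SL = K2 * (Ay_max - Ay_min)^(1/4), assuming stride
#' length is proportional to the vertical hip excursion, itself estimated
#' from the largest acceleration difference within the stride.
#'
#' @param ay Acceleration samples over one stride (raw units).
#' @param k2 Calibration constant (K2 = K).
#' @return Stride length in meters.
#' @export
sl_weinberg <- function(ay, k2 = calibration_constants()$k2) {
  ay <- check_window(ay, 2L)
  stopifnot(k2 > 0)
  k2 * (max(ay) - min(ay))^(1 / 4)
}

#' Stride length from the normalized mean acceleration (Scarlett)
#'
#' Third estimator: SL = K3 * mean((Ay_i - Ay_min) / (Ay_max - Ay_min)),
#' the correlation of min-max-normalized mean acceleration with step
#' length. Output lies in [0, K3]; a constant window has no defined
#' normalization and raises an error.
#'
#' @param ay Acceleration samples over one stride (raw units).
#' @param k3 Calibration constant (K3 = 2K).
#' @return Stride length in meters.
#' @export
sl_scarlett <- function(ay, k3 = calibration_constants()$k3) {
  ay <- check_window(ay, 2L)
  stopifnot(k3 > 0)
  rng <- max(ay) - min(ay)
  if (rng == 0) stop("constant window: zero acceleration range")
  k3 * mean((ay - min(ay)) / rng)
}

#' Calibrate the conversion coefficient K
#'
#' K is the mean of the element-wise ratios of estimated to real
#' distances over a set of calibration strides or walks.
#'
#' @param estimated Estimated distances (m).
#' @param real Reference distances (m), all positive.
#' @return The calibration coefficient k (scalar).
#' @export
calibrate_k <- function(estimated, real) {
  estimated <- as.numeric(estimated)
  real <- as.numeric(real)
  if (length(estimated) != length(real) || length(real) < 1L)
    stop("estimated and real must have equal positive length")
  if (any(real <= 0)) stop("real distances must be positive")
  mean(estimated / real)
}

#' Per-stride stride lengths from an insole recording
#'
#' Cuts the raw acceleration into the given stride windows and applies one
#' of the three estimators to each.
#'
#' @param rec An [insole_recording()].
#' @param boundaries data.frame with `start_s`, `end_s` stride boundaries.
#' @param approach 1 (mean absolute), 2 (Weinberg) or 3 (Scarlett).
#' @param constants A [calibration_constants()].
#' @return Numeric vector of stride lengths (m), one per stride.
#' @export
stride_lengths_insole <- function(rec, boundaries, approach = 3L,
                                  constants = calibration_constants()) {
  stopifnot(inherits(rec, "insole_recording"),
            approach %in% 1:3,
            inherits(constants, "calibration_constants"))
  b <- as.data.frame(boundaries)
  vapply(seq_len(nrow(b)), function(i) {
    w <- rec$ay[rec$time_s >= b$start_s[i] & rec$time_s <= b$end_s[i]]
    if (length(w) < 2L) stop("stride window contains fewer than 2 samples")
    switch(approach,
           sl_mean_abs(w, constants$k1),
           sl_weinberg(w, constants$k2),
           sl_scarlett(w, constants$k3))
  }, numeric(1))
}
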