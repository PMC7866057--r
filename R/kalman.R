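#' Kalman filter configuration for radar range tracking
#'
#' Settings for the discrete constant-acceleration Kalman filter used to
#' estimate gait velocity (and acceleration) from noisy radar range
#' measurements. The defaults are the values used throughout the package:
#' a 0.2 s tracking update, measurement-noise variance R = 0.04 m^2 and an
#' initial process-noise matrix Q0 = diag(0.04, 0.01, 0.01). Q is held
#' constant at Q0 after initialization.
#'
#' @param sample_interval_s Tracking update interval Ts in seconds (> 0).
#' @param measurement_noise Measurement-noise variance R in m^2 (> 0).
#' @param process_noise_init Diagonal of the 3x3 process-noise matrix Q0
#'   (position, velocity, acceleration terms), all entries >= 0.
#' @return An object of class `filter_config`.
#' @export
#' @examples
#' cfg <- filter_config()
#' cfg$sample_interval_s
filter_config <- function(sample_interval_s = 0.2,
                          measurement_noise = 0.04,
                          process_noise_init = c(0.04, 0.01, 0.01)) {
  stopifnot(is.numeric(sample_interval_s), length(sample_interval_s) == 1L,
            is.finite(sample_interval_s), sample_interval_s > 0)
  stopifnot(is.numeric(measurement_noise), length(measurement_noise) == 1L,
            is.finite(measurement_noise), measurement_noise > 0)
  stopifnot(is.numeric(process_noise_init), length(process_noise_init) == 3L,
            all(is.finite(process_noise_init)), all(process_noise_init >= 0))
  structure(
    list(sample_interval_s = sample_interval_s,
         measurement_noise = measurement_noise,
         process_noise_init = as.numeric(process_noise_init)),
    class = "filter_config")
}

#' Initial tracker state
#'
#' State of the range tracker: position (m), velocity (m/s), acceleration
#' (m/s^2) and their 3x3 covariance. By convention the filter is started at
#' the first measurement with zero velocity/acceleration and covariance Q0.
#'
#' @param position Position in meters.
#' @param velocity Velocity in m/s.
#' @param acceleration Acceleration in m/s^2.
#' @param covariance 3x3 symmetric positive semi-definite covariance matrix.
#' @return An object of class `track_state`.
#' @export
track_state <- function(position, velocity = 0, acceleration = 0,
                        covariance = diag(c(0.04, 0.01, 0.01))) {
  stopifnot(is.finite(position), is.finite(velocity), is.finite(acceleration))
  covariance <- as.matrix(covariance)
  stopifnot(identical(dim(covariance), c(3L, 3L)), all(is.finite(covariance)))
  if (max(abs(covariance - t(covariance))) > 1e-8)
    stop("covariance must be symmetric")
  if (min(eigen((covariance + t(covariance)) / 2, symmetric = TRUE,
                only.values = TRUE)$values) < -1e-8)
    stop("covariance must be positive semi-definite")
  structure(
    list(position = position, velocity = velocity,
         acceleration = acceleration,
         covariance = (covariance + t(covariance)) / 2),
    class = "track_state")
}

# transition matrix of the constant-acceleration model
kf_transition <- function(ts) {
  matrix(c(1, ts, ts^2 / 2,
           0, 1, ts,
           0, 0, 1), nrow = 3, byrow = TRUE)
}

#' One predict-update step of the range Kalman filter
#'
#' Propagates the state through the constant-acceleration model
#' (p <- p + v Ts + a Ts^2/2; v <- v + a Ts; a unchanged), then updates it
#' with a scalar range measurement (measurement matrix selects position).
#'
#' @param state A [track_state()].
#' @param measurement Measured range in meters (finite scalar).
#' @param config A [filter_config()].
#' @return The updated `track_state`.
#' @export
kf_step <- function(state, measurement, config = filter_config()) {
  stopifnot(inherits(state, "track_state"), inherits(config, "filter_config"))
  if (!is.numeric(measurement) || length(measurement) != 1L ||
      !is.finite(measurement))
    stop("measurement must be a finite scalar")
  ts <- config$sample_interval_s
  F_ <- kf_transition(ts)
  Q <- diag(config$process_noise_init)
  R <- config$measurement_noise
  x <- c(state$position, state$velocity, state$acceleration)

  # predict
  x_pred <- as.numeric(F_ %*% x)
  P_pred <- F_ %*% state$covariance %*% t(F_) + Q

  # update (H = [1 0 0])
  S <- P_pred[1, 1] + R
  K <- P_pred[, 1] / S
  innov <- measurement - x_pred[1]
  x_new <- x_pred + K * innov
  # Joseph form keeps the covariance symmetric PSD
  IKH <- diag(3)
  IKH[, 1] <- IKH[, 1] - K
  P_new <- IKH %*% P_pred %*% t(IKH) + (K %o% K) * R
  P_new <- (P_new + t(P_new)) / 2

  structure(
    list(position = x_new[1], velocity = x_new[2], acceleration = x_new[3],
         covariance = P_new),
    class = "track_state")
}

#' Kalman-filtered kinematics of a range series
#'
#' Runs the constant-acceleration Kalman filter over a uniformly sampled
#' range series and returns the filtered position, velocity and
#' acceleration at every sample. The filter is initialized at the first
#' measurement with zero velocity and acceleration and covariance Q0.
#'
#' @param positions Numeric vector of range measurements (meters), sampled
#'   every `config$sample_interval_s` seconds; at least 2 samples.
#' @param config A [filter_config()].
#' @return A data.frame with columns `position`, `velocity`, `acceleration`,
#'   one row per input sample.
#' @export
#' @examples
#' d <- 0.5 + 1.0 * (0:49) * 0.2
#' k <- estimate_kinematics(d)
#' tail(k$velocity, 1)  # close to 1 m/s
estimate_kinematics <- function(positions, config = filter_config()) {
  stopifnot(inherits(config, "filter_config"))
  positions <- as.numeric(positions)
  if (length(positions) < 2L) stop("need at least 2 samples")
  if (any(!is.finite(positions))) stop("positions must be finite")
  n <- length(positions)
  out_p <- out_v <- out_a <- numeric(n)
  st <- track_state(positions[1], 0, 0,
                    covariance = diag(config$process_noise_init))
  out_p[1] <- st$position
  for (k in 2:n) {
    st <- kf_step(st, positions[k], config)
    out_p[k] <- st$position
    out_v[k] <- st$velocity
    out_a[k] <- st$acceleration
  }
  data.frame(position = out_p, velocity = out_v, acceleration = out_a)
}
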