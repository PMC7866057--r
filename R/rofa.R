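#' Baseline gait statistics
#'
#' Per-parameter mean and standard deviation against which deviations are
#' scored, typically pooled over multiple strides of several reference
#' TUG trials (self-baseline) or from control subjects.
#'
#' @param means Named numeric vector of per-parameter means.
#' @param sds Named numeric vector of per-parameter standard deviations
#'   (> 0), same names.
#' @param provenance Free-text note ("self-baseline" or "control-group").
#' @return Object of class `baseline_stats`.
#' @export
baseline_stats <- function(means, sds, provenance = "self-baseline") {
  stopifnot(is.numeric(means), is.numeric(sds),
            length(means) == length(sds), length(means) >= 1L,
            !is.null(names(means)), identical(names(means), names(sds)))
  if (any(!is.finite(means)) || any(!is.finite(sds)) || any(sds <= 0))
    stop("baseline SDs must be finite and positive")
  structure(list(means = means, sds = sds, provenance = provenance),
            class = "baseline_stats")
}

#' Deviation ratio of a gait parameter
#'
#' Number of baseline standard deviations separating the measured value
#' from the baseline mean: Rk = |(Gk - GkM) / sigma_k|.
#'
#' @param gk Measured parameter value.
#' @param mean_k Baseline mean GkM.
#' @param sd_k Baseline standard deviation sigma_k (> 0).
#' @return Non-negative ratio Rk.
#' @export
compute_ratio <- function(gk, mean_k, sd_k) {
  stopifnot(is.finite(gk), is.finite(mean_k), is.finite(sd_k))
  if (sd_k <= 0) stop("baseline standard deviation must be positive")
  abs((gk - mean_k) / sd_k)
}

#' Per-parameter gait-deviation score
#'
#' Sk = 100 - 10 Rk, clamped to [0, 100]: 100 means the parameter sits at
#' its baseline mean, and every 10 points below 100 is one standard
#' deviation of deviation.
#'
#' @param rk Deviation ratio (>= 0).
#' @return Score in [0, 100].
#' @export
compute_sk <- function(rk) {
  if (any(!is.finite(rk)) || any(rk < 0))
    stop("deviation ratio must be non-negative")
  pmin(100, pmax(0, 100 - 10 * rk))
}

#' Composite TUG score
#'
#' Convex combination of the per-parameter scores: TUGscore = sum Wk Sk,
#' with equal weights by default.
#'
#' @param sk_values Per-parameter scores in [0, 100].
#' @param weights Non-negative weights summing to 1 (default equal).
#' @return Composite score in [0, 100].
#' @export
compute_tug_score <- function(sk_values, weights = NULL) {
  sk_values <- as.numeric(sk_values)
  if (length(sk_values) == 0L) stop("no scores to combine")
  if (is.null(weights)) weights <- rep(1 / length(sk_values),
                                       length(sk_values))
  if (length(weights) != length(sk_values))
    stop("weights and scores must have equal length")
  if (any(weights < 0) || abs(sum(weights) - 1) > 1e-9)
    stop("weights must be non-negative and sum to 1")
  sum(weights * sk_values)
}

#' Risk band of a TUG score
#'
#' Maps the 0-100 composite score to five bands: below 25 very high risk,
#' 25-50 high, 50-75 medium, 75-100 low, and exactly 100 very low.
#'
#' @param score Composite score in [0, 100].
#' @return One of "very high", "high", "medium", "low", "very low".
#' @export
classify_risk <- function(score) {
  if (!is.finite(score) || score < 0 || score > 100)
    stop("score must lie in [0, 100]")
  if (score == 100) "very low"
  else if (score >= 75) "low"
  else if (score >= 50) "medium"
  else if (score >= 25) "high"
  else "very high"
}

#' Build baseline statistics from reference trials
#'
#' Pools all strides of all reference trials per parameter and computes
#' the mean and sample standard deviation (n - 1 denominator, suited to
#' the small numbers of baseline trials). A parameter with zero pooled
#' variance is flagged and excluded from scoring with a warning.
#'
#' @param trials List of per-trial data.frames of per-stride gait
#'   parameters (as from [compute_gait_parameters()]).
#' @return A [baseline_stats()] with an `excluded` attribute naming any
#'   zero-variance parameters.
#' @export
build_baseline <- function(trials) {
  if (!is.list(trials) || length(trials) < 1L)
    stop("need at least one reference trial")
  if (inherits(trials, "data.frame")) trials <- list(trials)
  pooled <- do.call(rbind, lapply(trials, as.data.frame))
  params <- names(pooled)[vapply(pooled, is.numeric, logical(1))]
  if (nrow(pooled) < 2L) stop("need at least 2 pooled strides")
  means <- vapply(params, function(p) mean(pooled[[p]]), numeric(1))
  sds <- vapply(params, function(p) stats::sd(pooled[[p]]), numeric(1))
  bad <- params[sds <= 0]
  if (length(bad)) {
    warning("zero pooled variance, excluded from scoring: ",
            paste(bad, collapse = ", "))
    keep <- sds > 0
    means <- means[keep]; sds <- sds[keep]
  }
  if (length(means) == 0L) stop("no parameter with positive variance")
  b <- baseline_stats(means, sds)
  attr(b, "excluded") <- bad
  b
}

#' Score a TUG trial against a baseline
#'
#' Computes the per-stride, per-parameter deviation scores, averages them
#' across strides for each parameter, and combines the per-parameter
#' scores into the composite 0-100 TUG score with its risk band.
#' Alternatively (`aggregate = "trial_mean"`), the trial-mean parameter
#' value is scored directly.
#'
#' @param trial data.frame of per-stride gait parameters.
#' @param baseline A [baseline_stats()].
#' @param weights Optional weights over the scored parameters (default
#'   equal).
#' @param aggregate "per_stride" (score each stride then average) or
#'   "trial_mean".
#' @return Object of class `rofa_result`: `per_parameter` data.frame
#'   (`parameter`, `rk`, `sk`, `weight`), `tug_score`, `risk_band`,
#'   `n_parameters`, `n_strides`.
#' @export
score_trial <- function(trial, baseline, weights = NULL,
                        aggregate = c("per_stride", "trial_mean")) {
  aggregate <- match.arg(aggregate)
  stopifnot(inherits(baseline, "baseline_stats"))
  trial <- as.data.frame(trial)
  params <- intersect(names(baseline$means), names(trial))
  if (length(params) == 0L)
    stop("no overlap between trial parameters and baseline")
  if (nrow(trial) < 1L) stop("trial has no strides")
  sk <- vapply(params, function(p) {
    if (aggregate == "per_stride") {
      mean(vapply(trial[[p]], function(g)
        compute_sk(compute_ratio(g, baseline$means[[p]],
                                 baseline$sds[[p]])), numeric(1)))
    } else {
      compute_sk(compute_ratio(mean(trial[[p]]), baseline$means[[p]],
                               baseline$sds[[p]]))
    }
  }, numeric(1))
  rk <- vapply(params, function(p) {
    g <- if (aggregate == "per_stride") trial[[p]] else mean(trial[[p]])
    mean(vapply(g, compute_ratio, numeric(1),
                mean_k = baseline$means[[p]], sd_k = baseline$sds[[p]]))
  }, numeric(1))
  if (is.null(weights)) weights <- rep(1 / length(params), length(params))
  score <- compute_tug_score(sk, weights)
  structure(list(
    per_parameter = data.frame(parameter = params, rk = rk, sk = sk,
                               weight = weights, row.names = NULL),
    tug_score = score,
    risk_band = classify_risk(score),
    n_parameters = length(params),
    n_strides = nrow(trial)), class = "rofa_result")
}

#' @export
print.rofa_result <- function(x, ...) {
  cat(sprintf("ROFA / TUG score: %.1f (%s risk), %d parameters, %d strides\n",
              x$tug_score, x$risk_band, x$n_parameters, x$n_strides))
  print(x$per_parameter)
  invisible(x)
}

#' Read / write baseline statistics as JSON
#'
#' JSON of the form
#' `{"parameters": {"stride_length_m": {"mean": ..., "sd": ...}, ...}}`.
#'
#' @param path File path.
#' @return `read_baseline_json` returns a [baseline_stats()].
#' @export
read_baseline_json <- function(path) {
  obj <- jsonlite::fromJSON(path)
  p <- obj$parameters
  if (is.null(p) || length(p) == 0L) stop("no parameters in baseline JSON")
  means <- vapply(p, function(e) as.numeric(e$mean), numeric(1))
  sds <- vapply(p, function(e) as.numeric(e$sd), numeric(1))
  baseline_stats(means, sds,
                 provenance = if (!is.null(obj$provenance)) obj$provenance
                              else "self-baseline")
}

#' @rdname read_baseline_json
#' @param baseline A [baseline_stats()].
#' @export
write_baseline_json <- function(baseline, path) {
  stopifnot(inherits(baseline, "baseline_stats"))
  params <- lapply(seq_along(baseline$means), function(i)
    list(mean = unname(baseline$means[i]), sd = unname(baseline$sds[i])))
  names(params) <- names(baseline$means)
  jsonlite::write_json(list(parameters = params,
                            provenance = baseline$provenance),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
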