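# simulated-trial cache so expensive fixtures are built once per run

.trial_cache <- new.env(parent = emptyenv())

noise_free_params <- function(seed, ...) {
  sim_params(seed = seed, radar_noise_sd_m = 0, ay_noise_sd = 0,
             force_noise_sd = 0, ...)
}

cached_trial <- function(key, params) {
  if (is.null(.trial_cache[[key]]))
    .trial_cache[[key]] <- simulate_tug(params)
  .trial_cache[[key]]
}

clean_trial <- function(seed = 42)
  cached_trial(paste0("clean", seed), noise_free_params(seed))

noisy_trial <- function(seed = 42)
  cached_trial(paste0("noisy", seed), sim_params(seed = seed))

event_errors <- function(truth, ev) {
  abs(c(ev$t0 - truth$t0, ev$t1 - truth$t1, ev$t2 - truth$t2,
        ev$t3 - truth$t3, ev$t4 - truth$t4, ev$t5 - truth$t5))
}

interval_iou <- function(a, b) {
  inter <- max(0, min(a[2], b[2]) - max(a[1], b[1]))
  inter / (max(a[2], b[2]) - min(a[1], b[1]))
}

# brute-force oracle: full enumeration of sign assignments of the ranks
wilcoxon_oracle_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  mu <- n * (n + 1) / 4
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  sums <- as.numeric(signs %*% r)
  mean(abs(sums - mu) >= abs(w_obs - mu) - 1e-9)
}

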