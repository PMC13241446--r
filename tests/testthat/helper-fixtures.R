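# Shared fixtures, all built in code.

# Experimental and model-predicted tau at the four calibration time points,
# as published for this system.
published_fit_pairs <- function() {
  tibble::tibble(
    time_days = c(1, 7, 60, 180),
    observed = c(0.0032, 0.0048, 0.0085, 0.2533),
    predicted = c(0.00388, 0.00448, 0.00794, 0.25376)
  )
}

# The published optimized kinetic constants for this system.
published_params <- function() {
  kinetic_params(v0 = 0.0472197, J0 = 1.12609e-5, kv = 2.89573e-6, kJ = 3.14002e-6)
}

# Ground truth for parameter-recovery experiments: saturates around day 150,
# so a 15-day grid up to 150 days samples the whole sigmoid.
recovery_truth <- function() kinetic_params(v0 = 0.05, J0 = 1e-5, kv = 0.01, kJ = 0.005)

recovery_obs <- function() {
  times <- seq(15, 150, by = 15)
  observation_series(times, transformed_fraction(times, recovery_truth()))
}

# Desk-scale search configuration for tests.
quick_config <- function(seed, n_samples = 4000, n_restarts = 3, ...) {
  search_config(seed = seed, n_samples = n_samples, n_restarts = n_restarts, ...)
}

# Independent root-finding oracle for the correction factor: plain interval
# halving on the mean equation, written without reference to the package's
# solver internals.
oracle_correction <- function(w, ye, alpha = 0.35, A = 1, iters = 200) {
  a <- (A * w)^4 * ye
  target <- alpha * (1 - exp(-ye))
  lo <- 0
  hi <- 1
  while (mean(1 - exp(-hi * a)) < target) hi <- hi * 2
  for (i in seq_len(iters)) {
    mid <- (lo + hi) / 2
    if (mean(1 - exp(-mid * a)) < target) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

# Small focal synthetic mesh reused across spatial/atrophy tests.
focal_mesh <- function(dims = c(10, 10, 10), seed = 42, noise_sd = 0.01) {
  generate_synthetic_field(dims = dims, seed = seed, noise_sd = noise_sd)
}
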