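test_that("mse objective matches direct arithmetic and encodes failures", {
  obs <- murine_tbi_observations()
  # a model that predicts zero everywhere scores the mean squared observation
  zero_model <- kinetic_params(v0 = 1e-8, J0 = 0, kv = 0, kJ = 0)
  expect_equal(mse_objective(zero_model, obs), mean(obs$tau_at_percent^2))
  # reproducing the observations exactly gives zero
  truth <- recovery_truth()
  syn <- recovery_obs()
  expect_equal(mse_objective(truth, syn), 0)
  # overflow inside the model becomes the finite penalty
  expect_equal(mse_objective(kinetic_params(1, 1, kv = 10, kJ = 10), obs), 1e12)
})

test_that("global search is seeded, ranked, and beats the trivial baseline", {
  obs <- murine_tbi_observations()
  cfg <- quick_config(seed = 11, n_samples = 2000)
  a <- global_search(obs, cfg)
  b <- global_search(obs, cfg)
  expect_identical(a, b)
  expect_true(!is.unsorted(a$objective))
  expect_lt(a$objective[1], mean(obs$tau_at_percent^2))
  one <- global_search(obs, quick_config(seed = 1, n_samples = 1))
  expect_equal(nrow(one), 1L)
})

test_that("simplex refinement descends from a perturbed start", {
  syn <- recovery_obs()
  truth <- recovery_truth()
  cfg <- quick_config(seed = 3)
  start <- kinetic_params(
    v0 = truth$v0, J0 = truth$J0 * 1.05^3,
    kv = truth$kv * 1.05, kJ = truth$kJ * 0.95
  )
  f0 <- mse_objective(start, syn)
  res <- refine(start, syn, cfg)
  expect_lt(res$objective, f0)
  expect_true(res$converged)
  # refinement never worsens the objective, from any start
  rough <- kinetic_params(0.01, 1e-6, -0.02, 0.03)
  expect_lte(refine(rough, syn, cfg)$objective, mse_objective(rough, syn))
})

test_that("goodness of fit reproduces the calibration-table statistics", {
  t1 <- published_fit_pairs()
  gof <- goodness_of_fit(t1$observed, t1$predicted)
  # independently recomputed from the printed pairs
  res <- t1$observed - t1$predicted
  expect_equal(gof$rmse, sqrt(mean(res^2)))
  expect_equal(gof$r2, 1 - sum(res^2) / sum((t1$observed - mean(t1$observed))^2))
  perfect <- goodness_of_fit(c(1, 2, 3), c(1, 2, 3))
  expect_equal(perfect$rmse, 0)
  expect_equal(perfect$r2, 1)
  expect_error(goodness_of_fit(c(1, 1), c(1, 2)), class = "tauavrami_error_invalid")
  expect_error(goodness_of_fit(1, 1), class = "tauavrami_error_invalid")
})

test_that("calibrate is deterministic and dominates the search stage", {
  obs <- murine_tbi_observations()
  cfg <- quick_config(seed = 5, n_samples = 800, n_restarts = 2)
  f1 <- calibrate(obs, cfg)
  f2 <- calibrate(obs, cfg)
  expect_identical(unclass(f1$params), unclass(f2$params))
  expect_identical(f1$rmse, f2$rmse)
  # the refined optimum is at least as good as every random candidate
  cands <- global_search(obs, cfg)
  expect_lte(f1$objective, min(cands$objective))
  expect_equal(f1$objective_trace$stage, c("global_search", "nelder_mead"))
  expect_true(all(diff(f1$objective_trace$objective) <= 0))
})

test_that("noise-free synthetic trajectories recover the identifiable parameters", {
  truth <- recovery_truth()
  syn <- recovery_obs()
  C_true <- truth$J0 * truth$v0^3
  fit <- calibrate(syn, quick_config(seed = 21))
  C_hat <- fit$params$J0 * fit$params$v0^3
  expect_lt(abs(C_hat - C_true) / C_true, 0.05)
  expect_lt(abs(fit$params$kv - truth$kv), 0.05)
  expect_lt(abs(fit$params$kJ - truth$kJ), 0.05)
  expect_lt(fit$rmse, 1e-6)
})

test_that("two points on a constant-rate curve are fitted essentially exactly", {
  p <- kinetic_params(v0 = 0.01, J0 = 1e-4, kv = 0, kJ = 0)
  times <- c(100, 200)
  obs <- observation_series(times, transformed_fraction(times, p))
  fit <- calibrate(obs, quick_config(seed = 9, n_samples = 2000))
  expect_lt(fit$rmse, 1e-8)
})

test_that("tidiers expose parameters and fit quality", {
  fit <- calibrate(murine_tbi_observations(),
                   quick_config(seed = 2, n_samples = 500, n_restarts = 1))
  td <- tidy(fit)
  expect_setequal(td$term, c("v0", "J0", "kv", "kJ", "C"))
  expect_false(td$identifiable[td$term == "v0"])
  gl <- glance(fit)
  expect_named(
    gl, c("rmse", "r.squared", "objective", "converged", "n_obs", "seed", "alpha")
  )
  aug <- augment(fit)
  expect_equal(aug$residual, aug$tau_at_percent - aug$predicted)
})

test_that("observation series and config enforce their invariants", {
  expect_error(observation_series(c(1, 1), c(0.1, 0.2)), class = "tauavrami_error_invalid")
  expect_error(observation_series(c(0, 1), c(0.1, 0.2)), class = "tauavrami_error_invalid")
  expect_error(observation_series(c(1, 2), c(0.1, 0.4)), class = "tauavrami_error_invalid")
  expect_error(search_config(), class = "tauavrami_error_invalid")
  expect_error(search_config(seed = 1, n_samples = 0), class = "tauavrami_error_invalid")
  expect_error(
    search_config(seed = 1, bounds = list(log_c = c(1, -1), kv = c(0, 1), kJ = c(0, 1))),
    class = "tauavrami_error_invalid"
  )
})
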