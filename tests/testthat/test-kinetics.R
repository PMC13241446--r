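test_that("nucleation rate and growth velocity follow the exponential laws", {
  p <- kinetic_params(v0 = 3, J0 = 5, kv = -0.5, kJ = 0.1)
  # at time zero both reduce to their reference values
  expect_equal(nucleation_rate(0, p), 5)
  expect_equal(growth_velocity(0, p), 3)
  # zero modulation freezes the rates at any time
  p0 <- kinetic_params(v0 = 3, J0 = 5, kv = 0, kJ = 0)
  expect_equal(nucleation_rate(100, p0), 5)
  expect_equal(growth_velocity(100, p0), 3)
  # direct evaluations
  expect_equal(nucleation_rate(10, kinetic_params(1, 2, kJ = 0.1)), 2 * exp(1))
  expect_equal(growth_velocity(2, kinetic_params(1, 1, kv = -0.5)), exp(-1))
  expect_error(nucleation_rate(-1, p), class = "tauavrami_error_invalid")
  expect_error(growth_velocity(NaN, p), class = "tauavrami_error_invalid")
})

test_that("domain radius integrates the velocity and degrades to the linear limit", {
  expect_equal(domain_radius(4, 4, kinetic_params(2, 1, kv = 0.3)), 0)
  # constant-velocity limit v0 (t - tp)
  expect_equal(domain_radius(4, 1, kinetic_params(2, 1, kv = 0)), 6)
  expect_equal(domain_radius(4, 1, kinetic_params(2, 1, kv = 1e-13)), 6, tolerance = 1e-9)
  # doubling-velocity case (v0/kv)(2 - 1) and its quadrature cross-check
  p <- kinetic_params(1, 1, kv = log(2))
  expect_equal(domain_radius(1, 0, p), 1 / log(2))
  quad <- integrate(function(s) growth_velocity(s, p), 0, 1, rel.tol = 1e-12)$value
  expect_equal(domain_radius(1, 0, p), quad, tolerance = 1e-10)
  expect_error(domain_radius(1, 2, p), class = "tauavrami_error_invalid")
})

test_that("domain volume is the sphere of the accumulated radius", {
  p <- kinetic_params(1, 1, kv = 0)
  expect_equal(domain_volume(0, 0, p), 0)
  expect_equal(domain_volume(1, 0, p), 4 * pi / 3) # unit sphere
  expect_equal(domain_volume(2, 0, kinetic_params(1, 1, kv = 1e-13)),
               (4 * pi / 3) * 8, tolerance = 1e-9)
})

test_that("extended volume: quadrature oracle and closed form agree", {
  # constant-rate limit: (4 pi / 3) integral of (1 - t')^3 = pi / 3
  p_const <- kinetic_params(1, 1, kv = 1e-12, kJ = 1e-12)
  expect_equal(extended_volume_quadrature(1, p_const), pi / 3, tolerance = 1e-8)
  expect_equal(extended_volume(1, p_const), pi / 3, tolerance = 1e-8)
  expect_equal(extended_volume_quadrature(0, p_const), 0)
  expect_equal(extended_volume(0, p_const), 0)

  # closed form against the quadrature oracle over random parameter draws
  withr::with_seed(7, {
    for (i in 1:50) {
      p <- kinetic_params(
        v0 = 10^runif(1, -6, -1), J0 = 10^runif(1, -6, -1),
        kv = runif(1, -0.05, 0.05), kJ = runif(1, -0.05, 0.05)
      )
      for (t in c(1, 10, 100)) {
        q <- extended_volume_quadrature(t, p)
        expect_lt(abs(extended_volume(t, p) - q) / max(q, 1e-30), 1e-6)
      }
    }
  })

  # sensitivity baseline at t = 100 matches the oracle tightly
  pb <- kinetic_params(1e-3, 1e-3, 1e-3, 1e-3)
  q <- extended_volume_quadrature(100, pb)
  expect_lt(abs(extended_volume(100, pb) - q) / q, 1e-8)
})

test_that("large opposing modulation rates stay finite in the closed form", {
  # kJ t is huge while 3 kv t + kJ t is moderate: the bracket must combine
  # the exponentials before any one of them overflows
  p <- kinetic_params(0.0472197, 0.7537, kv = -1.30396, kJ = 3.94324)
  ye <- extended_volume(c(1, 50, 350), p)
  expect_true(all(is.finite(ye)))
  expect_true(all(diff(ye) > 0))
  q <- extended_volume_quadrature(1, p)
  expect_lt(abs(ye[1] - q) / q, 1e-8)
})

test_that("extended volume is continuous across the quadrature switchover", {
  # the branch switch sits at |kv| t = 1e-2; straddle it at t = 10
  t <- 10
  lo <- extended_volume(t, kinetic_params(0.01, 0.02, kv = 0.00099999, kJ = 0.013))
  hi <- extended_volume(t, kinetic_params(0.01, 0.02, kv = 0.00100001, kJ = 0.013))
  expect_lt(abs(hi - lo) / lo, 1e-6)
})

test_that("exponential overflow raises a typed error instead of Inf", {
  p <- kinetic_params(1, 1, kv = 10, kJ = 10)
  expect_error(extended_volume(300, p), class = "tauavrami_error_overflow")
  expect_error(nucleation_rate(100, kinetic_params(1, 1, kJ = 10)),
               class = "tauavrami_error_overflow")
})

test_that("transformed fraction saturates strictly below alpha", {
  p <- kinetic_params(1e-3, 1e-3, 1e-3, 1e-3)
  expect_equal(transformed_fraction(0, p), 0)
  # direct evaluation at Ye = 1
  expect_equal(0.35 * -expm1(-1), 0.35 * (1 - exp(-1)))
  x <- transformed_fraction(c(1, 7, 60, 180, 365), p)
  expect_true(all(diff(x) > 0))
  expect_true(all(x < 0.35))
  # deep saturation approaches the bound
  psat <- kinetic_params(1, 1, kv = 0.05, kJ = 0.05)
  expect_equal(transformed_fraction(200, psat), 0.35)
})

test_that("trajectory is the vectorized scalar evaluation and is monotone", {
  p <- kinetic_params(1e-3, 1e-3, 1e-3, 1e-3)
  grid <- c(0, 1, 7, 60, 180, 365)
  traj <- kjma_trajectory(grid, p)
  expect_named(traj, c("time_days", "ye", "x"))
  expect_equal(traj$ye, vapply(grid, function(t) extended_volume(t, p), numeric(1)))
  expect_equal(traj$x, vapply(grid, function(t) transformed_fraction(t, p), numeric(1)))
  expect_true(all(diff(traj$x) >= 0))
  expect_true(all(diff(traj$ye) >= 0))
  expect_equal(kjma_trajectory(0, p), tibble::tibble(time_days = 0, ye = 0, x = 0))
  expect_error(kjma_trajectory(c(3, 1), p), class = "tauavrami_error_invalid")
})

test_that("parameter constructor enforces invariants", {
  expect_error(kinetic_params(0, 1), class = "tauavrami_error_invalid")
  expect_error(kinetic_params(1, -1), class = "tauavrami_error_invalid")
  expect_error(kinetic_params(1, 1, kv = Inf), class = "tauavrami_error_invalid")
  expect_s3_class(kinetic_params(1, 0, -1, -1), "kinetic_params")
})
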