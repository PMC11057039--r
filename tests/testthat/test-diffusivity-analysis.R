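# MSD estimation, long-time diffusion extraction, and the linear slowdown fit.

test_that("MSD estimator matches the brute-force double loop exactly", {
  set.seed(101)
  arr <- array(rnorm(15 * 4 * 3), dim = c(15, 4, 3))
  traj <- make_trajectory(arr, dt = 0.5)
  curve <- compute_msd(traj, max_lag_fraction = 0.99)
  for (lag in c(1, 3, 7, 13)) {
    expect_equal(curve$msd[curve$lag_times == lag * 0.5],
                 oracle_msd_at_lag(arr, lag), tolerance = 1e-12)
  }
  expect_identical(curve$msd[1], 0)           # msd(0) = 0
  expect_true(all(diff(curve$lag_times) > 0)) # lags strictly increasing
})

test_that("constructed motions give their closed-form MSDs", {
  # stationary particles: msd identically zero
  still <- make_trajectory(array(2, dim = c(12, 3, 3)), dt = 1)
  expect_true(all(compute_msd(still)$msd == 0))
  # ballistic drift x = v t: msd = v^2 tau^2 exactly
  v <- c(1.5, -0.5, 2)
  tt <- 0:20
  arr <- array(0, dim = c(21, 1, 3))
  for (k in 1:3) arr[, 1, k] <- v[k] * tt
  curve <- compute_msd(make_trajectory(arr, dt = 1), max_lag_fraction = 0.5)
  expect_equal(curve$msd, sum(v^2) * curve$lag_times^2, tolerance = 1e-10)
})

test_that("long_time_d recovers exact and random-walk diffusivities", {
  # exact line msd = 6 D tau -> D returned with ~zero uncertainty
  tau <- seq(0, 10, by = 0.5)
  fake <- structure(list(lag_times = tau, msd = 6 * 42 * tau,
                         n_pairs = rep(100L, length(tau)),
                         species = "x", block_msd = NULL),
                    class = "msd_curve")
  est <- long_time_d(fake)
  expect_equal(est$d, 42, tolerance = 1e-12)
  expect_lt(est$se, 1e-8)

  # synthetic free walk of known D (independent generator oracle)
  traj <- generate_free_walk(100, n_steps = 1e4, dt = 0.01, seed = 7,
                             n_particles = 10)
  est2 <- long_time_d(compute_msd(traj, max_lag_fraction = 0.1))
  expect_lt(abs(est2$d - 100), 3 * est2$se)
})

test_that("subdiffusive input triggers the non-converged warning", {
  tau <- seq(0, 10, by = 0.25)
  sub <- structure(list(lag_times = tau, msd = 6 * sqrt(tau),
                        n_pairs = rep(50L, length(tau)),
                        species = "x", block_msd = NULL),
                   class = "msd_curve")
  expect_warning(long_time_d(sub), "not converged")
  short <- structure(list(lag_times = 0:2, msd = c(0, 6, 12),
                          n_pairs = rep(5L, 3), species = "x",
                          block_msd = NULL), class = "msd_curve")
  expect_error(long_time_d(short), "fewer than 5")
})

test_that("fit_kappa recovers exact slopes with the intercept pinned at 1", {
  phi <- c(0, 0.1, 0.2, 0.3)
  f1 <- fit_kappa(slowdown_curve(phi, 1 - 0.5 * phi))
  expect_equal(f1$kappa, 0.5, tolerance = 1e-12)
  expect_equal(f1$r_squared, 1, tolerance = 1e-12)
  f2 <- fit_kappa(slowdown_curve(phi, 1 - 2 * phi))
  expect_equal(f2$kappa, 2, tolerance = 1e-12)

  # invariant to uniform rescaling of the sigmas
  set.seed(5)
  noisy <- 1 - 1.3 * phi + c(0, rnorm(3, sd = 0.01))
  fa <- fit_kappa(slowdown_curve(phi, noisy, sigma = rep(0.01, 4)))
  fb <- fit_kappa(slowdown_curve(phi, noisy, sigma = rep(0.07, 4)))
  expect_equal(fa$kappa, fb$kappa, tolerance = 1e-12)
  expect_equal(fa$kappa_se, fb$kappa_se, tolerance = 1e-12)

  expect_error(fit_kappa(slowdown_curve(c(0.1, 0.2, 0.3), 1 - c(0.1, 0.2, 0.3))),
               "anchor")
  expect_error(fit_kappa(slowdown_curve(c(0, 0.1), c(1, 0.9))), "3 distinct")
})

test_that("a single noisy slowdown table is fit close to its truth", {
  tab <- generate_slowdown_table("linear_phi", list(kappa = 1.3),
                                 n_points = 5, noise_sd = 0.01, seed = 17)
  f <- fit_kappa(tab)
  expect_lt(abs(f$kappa - 1.3), 4 * f$kappa_se)
})
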