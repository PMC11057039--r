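# Synthetic PGSTE-NMR attenuation data and diffusion-coefficient fitting.

test_that("acquisition parameters are validated", {
  expect_error(pgste_acquisition(delta_ms = 100, Delta_ms = 100), "smaller")
  expect_error(pgste_acquisition(gradients = c(0, 0.1, 0.2)), "at least 5")
  expect_error(pgste_acquisition(gradients = c(0, 0.2, 0.1, 0.3, 0.4)),
               "strictly increasing")
})

test_that("Stejskal-Tanner attenuation matches scalar hand arithmetic", {
  acq <- pgste_acquisition(gamma = 2.6752e8, delta_ms = 2, Delta_ms = 100,
                           gradients = seq(0, 0.5, length.out = 6))
  expect_identical(stejskal_tanner(0, acq, 1e-9), 1)
  expect_identical(stejskal_tanner(0.3, acq, 0), 1)
  # independent arithmetic: b = gamma^2 g^2 delta^2 (Delta - delta/3) in SI
  b_hand <- (2.6752e8)^2 * 0.1^2 * (2e-3)^2 * (100e-3 - 2e-3 / 3)
  expect_equal(stejskal_tanner(0.1, acq, 1e-9), exp(-1e-9 * b_hand),
               tolerance = 1e-12)
  # monotone decreasing in g, D, delta and Delta individually
  expect_true(all(diff(stejskal_tanner(seq(0, 0.5, 0.05), acq, 1e-9)) < 0))
  expect_gt(stejskal_tanner(0.2, acq, 1e-10), stejskal_tanner(0.2, acq, 1e-9))
  acq_d <- pgste_acquisition(delta_ms = 4, Delta_ms = 100)
  expect_gt(stejskal_tanner(0.2, pgste_acquisition(delta_ms = 2), 1e-9),
            stejskal_tanner(0.2, acq_d, 1e-9))
  acq_D <- pgste_acquisition(delta_ms = 2, Delta_ms = 200)
  expect_gt(stejskal_tanner(0.2, pgste_acquisition(Delta_ms = 100), 1e-9),
            stejskal_tanner(0.2, acq_D, 1e-9))
})

test_that("simulated series are exact without noise and seeded with it", {
  acq <- pgste_acquisition()
  clean <- simulate_series(2e-10, acq, noise_sd = 0, seed = 1)
  expect_equal(clean$signal, stejskal_tanner(acq$gradients, acq, 2e-10))
  a <- simulate_series(2e-10, acq, noise_sd = 0.02, seed = 5)
  b <- simulate_series(2e-10, acq, noise_sd = 0.02, seed = 5)
  expect_identical(a$signal, b$signal)
  # empirical noise sd over many draws within 5% of nominal
  resid <- unlist(lapply(1:625, function(s)
    simulate_series(2e-10, acq, 0.02, seed = s)$signal -
      stejskal_tanner(acq$gradients, acq, 2e-10)))
  expect_equal(sd(resid), 0.02, tolerance = 0.05)
})

test_that("fit_attenuation inverts the model and validates its input", {
  clean <- simulate_series(2e-10, noise_sd = 0, seed = 1)
  fit <- fit_attenuation(clean)
  expect_lt(abs(fit$d - 2e-10) / 2e-10, 1e-6)
  clipped <- clean
  clipped$signal <- clipped$signal[1:3]
  clipped$acquisition$gradients <- clipped$acquisition$gradients[1:3]
  expect_error(fit_attenuation(clipped), "at least 5")
  bad <- clean
  bad$signal[10] <- -0.5
  expect_error(fit_attenuation(bad), "negative")
})

test_that("slowdown tables carry their truth and support round trips", {
  clean <- generate_slowdown_table("linear_phi", list(kappa = 0.5),
                                   n_points = 6, noise_sd = 0, seed = 1)
  expect_equal(clean$d_ratio, 1 - 0.5 * clean$phi_occ, tolerance = 1e-12)
  expect_equal(attr(clean, "truth")$kappa, 0.5)

  noisy <- generate_slowdown_table("linear_phi", list(kappa = 2),
                                   n_points = 6, noise_sd = 0.005, seed = 2)
  f <- fit_kappa(noisy)
  expect_lt(abs(f$kappa - 2), 2 * f$kappa_se + 0.01)
})

test_that("free walks are seeded and diffusively invariant under dt refinement", {
  a <- generate_free_walk(100, 1000, 0.01, seed = 3)
  b <- generate_free_walk(100, 1000, 0.01, seed = 3)
  expect_identical(a$unwrapped, b$unwrapped)

  coarse <- generate_free_walk(50, 5000, 0.02, seed = 4, n_particles = 10)
  fine <- generate_free_walk(50, 10000, 0.01, seed = 4, n_particles = 10)
  ec <- long_time_d(compute_msd(coarse, max_lag_fraction = 0.1))
  ef <- long_time_d(compute_msd(fine, max_lag_fraction = 0.1))
  expect_lt(abs(ec$d - ef$d), 3 * sqrt(ec$se^2 + ef$se^2))
  expect_lt(abs(ec$d - 50), 3 * ec$se)
})
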