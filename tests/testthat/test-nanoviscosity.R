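# Size-dependent nanoviscosity: the intercrowder gap, effective radius
# interpolants, the exponential slowdown model, and its fitting.

test_that("psi_rcp and the hard-sphere gap match their defining identities", {
  expect_equal(psi_rcp(), 0.638 / (1 - 0.638), tolerance = 1e-15)
  expect_equal(round(psi_rcp(), 2), 1.76)
  expect_equal(0.5 / (1 - 0.5), 1)  # sanity of the phi/(1-phi) map
  # psi_rcp cancels exactly at random close packing
  expect_equal(xi_hard_sphere(5.1, 0.638), 5.1, tolerance = 1e-12)
  # monotone decreasing in phi
  phis <- seq(0.05, 0.9, by = 0.05)
  expect_true(all(diff(xi_hard_sphere(5.1, phis)) < 0))
  # hand arithmetic: R_g = 5.1 nm at the cytoplasm occupancy
  expect_equal(xi_hard_sphere(5.1, 0.426), 5.1 * (0.638 / 0.362) * (0.574 / 0.426),
               tolerance = 1e-12)
  expect_equal(xi_hard_sphere(5.1, 0.426), 12.11, tolerance = 1e-3)
  expect_error(xi_hard_sphere(5.1, 0), "strictly inside")
})

test_that("effective radius interpolates between tracer and crowder limits", {
  expect_equal(r_eff_standard(100 * 5.1, 5.1), 5.1, tolerance = 1e-4)
  expect_equal(r_eff_standard(0.01 * 5.1, 5.1), 0.051, tolerance = 1e-4)
  expect_equal(r_eff_standard(5.1, 5.1), 5.1 / sqrt(2), tolerance = 1e-12)
  # harmonic alternative shares both limits
  expect_equal(r_eff_standard(1000, 5.1, "harmonic"), 5.1, tolerance = 1e-2)
  # minimal length: reduces at r_min = 0, non-vanishing at R_H = 0
  rh <- seq(0, 10, by = 0.25)
  expect_identical(r_eff_modified(rh, 5.1, 0), r_eff_standard(rh, 5.1))
  expect_gt(r_eff_modified(0, 5.1, 0.3), 0)
  expect_equal(r_eff_modified(0, 5.1, 0.3), r_eff_standard(0.3, 5.1))
  # finite positive slope at the origin (numerical derivative)
  h <- 1e-6
  slope <- (r_eff_modified(h, 5.1, 0.3) - r_eff_modified(0, 5.1, 0.3)) / h
  expect_gt(slope, 0)
  expect_lt(slope, 2)
})

test_that("the slowdown model obeys its limits and small-size expansion", {
  p <- nanovisc_params(a = 1, b = 3, r_c_eff = 5.1, phi_occ = 0.3)
  expect_equal(d_ratio_nanovisc(0, p), 1, tolerance = 1e-12)
  p0 <- nanovisc_params(a = 1, b = 0, r_c_eff = 5.1, phi_occ = 0.3)
  expect_true(all(d_ratio_nanovisc(c(0, 1, 5, 20), p0) == 1))
  # strictly decreasing in R_H and in phi for b > 0
  rh <- seq(0.1, 15, by = 0.1)
  expect_true(all(diff(d_ratio_nanovisc(rh, p)) < 0))
  dphi <- vapply(c(0.1, 0.2, 0.3, 0.4), function(f)
    d_ratio_nanovisc(2, nanovisc_params(a = 1, b = 3, r_c_eff = 5.1,
                                        phi_occ = f)), numeric(1))
  expect_true(all(diff(dphi) < 0))
  # first-order expansion: |exp(-x) - (1 - x)| < 1e-4 at x = 1e-2
  x_target <- 1e-2
  reff <- r_eff_standard(0.05, 5.1)
  b_small <- x_target / (reff / p$xi)
  ps <- nanovisc_params(a = 1, b = b_small, r_c_eff = 5.1, xi = p$xi)
  expect_lt(abs(d_ratio_nanovisc(0.05, ps) - (1 - x_target)), 1e-4)
})

test_that("with a minimal length the model linearizes to the slowdown law", {
  # kappa(R_H) = lim_{phi->0} (1 - D/D0)/phi should be affine in R_H
  kappa_of <- function(rh) {
    p <- nanovisc_params(a = 1, b = 2, r_c_eff = 5.1, r_min = 0.3,
                         phi_occ = 1e-4)
    (1 - d_ratio_nanovisc(rh, p)) / 1e-4
  }
  rh <- c(0, 0.02, 0.04, 0.06, 0.08)
  k <- vapply(rh, kappa_of, numeric(1))
  expect_gt(k[1], 0)                      # non-vanishing point-tracer kappa
  expect_true(all(diff(k) > 0))           # kappa grows with tracer size
  second_diff <- diff(diff(k))
  expect_true(all(abs(second_diff) < 0.01 * max(abs(diff(k)))))
})

test_that("fitting recovers model parameters from its own curves", {
  truth <- nanovisc_params(a = 0.67, b = 3.7, r_c_eff = 12.1, phi_occ = 0.426)
  clean <- generate_slowdown_table("nanovisc_rh", truth, n_points = 10,
                                   noise_sd = 0, seed = 1)
  fit <- fit_nanovisc(clean, phi_occ = 0.426)
  expect_equal(fit$params$a, 0.67, tolerance = 0.01)
  expect_equal(fit$params$b, 3.7, tolerance = 0.01)
  expect_equal(fit$params$r_c_eff, 12.1, tolerance = 0.01)

  # fixed-exponent minimal-length mode recovers its own truth too
  truth8 <- nanovisc_params(a = 1, b = 2.5, r_c_eff = 8, r_min = 0.4,
                            phi_occ = 0.426)
  clean8 <- generate_slowdown_table("nanovisc_rh", truth8, n_points = 12,
                                    noise_sd = 0, seed = 2)
  fit8 <- fit_nanovisc(clean8, phi_occ = 0.426, fix_a = 1)
  expect_equal(fit8$params$b, 2.5, tolerance = 0.02)
  expect_equal(fit8$params$r_min, 0.4, tolerance = 0.05)

  # flat curve: b collapses to its lower bound at 0
  flat <- slowdown_curve(c(0.5, 1, 2, 4, 8), rep(1, 5),
                         abscissa_name = "r_h_nm")
  fitf <- fit_nanovisc(flat, phi_occ = 0.3)
  expect_lt(fitf$params$b, 1e-4)
  expect_error(fit_nanovisc(flat[1:3, ], phi_occ = 0.3), "at least 4")
})
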