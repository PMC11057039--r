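# Hard-sphere Brownian propagation: Euler step, overlap resolution, and
# trajectory contracts.

test_that("a zero timestep leaves the configuration unchanged", {
  cfg <- build_mixture(species("c", 5.1, 20), species("t", 0.8, 10), 0.05,
                       seed = 1)
  out <- euler_step(cfg, bd_params(timestep = 0, n_steps = 1))
  expect_equal(out$positions, cfg$positions, tolerance = 1e-14)
})

test_that("too-large timesteps are refused", {
  cfg <- build_mixture(species("c", 5.1, 0), species("t", 0.8, 5), 0,
                       box_edge = 40, seed = 1)
  expect_error(run_trajectory(cfg, bd_params(timestep = 1, n_steps = 10)),
               "timestep too large")
})

test_that("a single free particle recovers its input diffusivity", {
  cfg <- configuration(50, "t", 1, matrix(25, 1, 3))
  d0 <- sse_diffusivity(1, env298)
  traj <- run_trajectory(cfg, bd_params(n_steps = 2e4, sampling_interval = 20,
                                        seed = 21, env = env298))
  est <- long_time_d(compute_msd(traj, max_lag_fraction = 0.1))
  expect_lt(abs(est$d - d0), 3 * max(est$se, 0.05 * d0))
})

test_that("two free species diffuse in inverse proportion to their radii", {
  cfg <- build_mixture(species("big", 2, 0), rbind(species("big", 2, 40),
                                                   species("small", 1, 40)),
                       0, box_edge = 40, seed = 2)
  traj <- run_trajectory(cfg, bd_params(n_steps = 2e4, sampling_interval = 20,
                                        seed = 22, env = env298))
  d_big <- long_time_d(compute_msd(traj, "big", max_lag_fraction = 0.1))$d
  d_small <- long_time_d(compute_msd(traj, "small", max_lag_fraction = 0.1))$d
  expect_equal(d_small / d_big, 2, tolerance = 0.05)
})

test_that("overlap resolution restores contact with mobility-shared moves", {
  # overlap-free input is returned unchanged, bitwise
  ok <- build_mixture(species("c", 5.1, 30), NULL, 0.2, seed = 3)
  out <- resolve_overlaps(ok)
  expect_identical(out$positions, ok$positions)
  expect_identical(attr(out, "sweeps"), 0L)

  # two equal spheres at distance 1.5 separate to exactly 2, midpoint fixed
  pos <- rbind(c(10, 10, 10), c(11.5, 10, 10))
  cfg <- configuration(50, c("a", "a"), c(1, 1), pos, check_overlaps = FALSE)
  res <- resolve_overlaps(cfg)
  expect_equal(oracle_mi_dist(res$positions[1, ], res$positions[2, ], 50), 2,
               tolerance = 1e-12)
  expect_equal((res$positions[1, ] + res$positions[2, ]) / 2, c(10.75, 10, 10),
               tolerance = 1e-12)

  # D0 ratio 3:1 (radius ratio 1:3) splits the correction 3:1
  pos2 <- rbind(c(20, 20, 20), c(23, 20, 20))  # contact distance 4, overlap 1
  cfg2 <- configuration(60, c("s", "b"), c(1, 3), pos2, check_overlaps = FALSE)
  res2 <- resolve_overlaps(cfg2)
  m1 <- oracle_mi_dist(res2$positions[1, ], pos2[1, ], 60)
  m2 <- oracle_mi_dist(res2$positions[2, ], pos2[2, ], 60)
  expect_equal(m1 / m2, 3, tolerance = 1e-9)
  expect_equal(oracle_mi_dist(res2$positions[1, ], res2$positions[2, ], 60), 4,
               tolerance = 1e-12)
})

test_that("trajectories honor frame, determinism and hard-core contracts", {
  cfg <- build_mixture(species("c", 5.1, 40), species("t", 0.8, 20), 0.1,
                       seed = 4)
  # n_steps = 0 keeps only the initial frame
  t0 <- run_trajectory(cfg, bd_params(n_steps = 0, seed = 30))
  expect_equal(dim(t0$unwrapped)[1], 1)
  expect_equal(t0$times, 0)

  p <- bd_params(n_steps = 500, sampling_interval = 50, seed = 31)
  a <- run_trajectory(cfg, p)
  b <- run_trajectory(cfg, p)
  expect_identical(a$unwrapped, b$unwrapped)

  # no stored frame contains an overlap (exhaustive oracle per frame)
  for (f in seq_along(a$times))
    expect_gte(oracle_min_gap(trajectory_frame(a, f)), -1e-9)
  # unwrapped and wrapped coordinates agree modulo the box
  last <- dim(a$unwrapped)[1]
  expect_equal(a$unwrapped[last, , ] %% a$box_edge, a$final$positions,
               tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("crowding slows tracers relative to the free-diffusion control", {
  free <- simulate_state_point(0.8, 0, n_steps = 3e4, seed = 41,
                               box_edge_phi0 = 60)
  crowded <- simulate_state_point(0.8, 0.2, n_steps = 3e4, n_crowders = 60,
                                  seed = 42)
  expect_lt(crowded$d_ratio, free$d_ratio)
})
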