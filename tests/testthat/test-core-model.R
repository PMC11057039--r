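# Units, constants and the Stokes-Sutherland-Einstein relation.

test_that("SSE diffusivity matches direct hand arithmetic and scales as 1/R", {
  # independent hand calculation: D = kB*T/(6 pi eta R) in SI, then to nm^2/us
  d_si <- 1.380649e-23 * 298 / (6 * pi * 0.89e-3 * 1e-9)  # m^2/s for R = 1 nm
  expect_equal(sse_diffusivity(1, env298), d_si * 1e12, tolerance = 1e-12)
  expect_equal(sse_diffusivity(1, env298), 245.2497, tolerance = 1e-6)
  # 1/R scaling: doubling the radius exactly halves D
  expect_equal(sse_diffusivity(2, env298), sse_diffusivity(1, env298) / 2)
  expect_error(sse_diffusivity(-1, env298), "positive")
  expect_error(physical_environment(298, 0), "positive")
})

test_that("sse_diffusivity and hydrodynamic_radius_from_d are exact inverses", {
  radii <- c(0.28, 0.8, 1, 2.5, 5.1, 13)
  back <- hydrodynamic_radius_from_d(sse_diffusivity(radii, env298), env298)
  expect_equal(back, radii, tolerance = 1e-12)
  # hand value: D = 245 nm^2/us at 298 K / 0.89 mPa.s is a ~1 nm sphere
  expect_equal(hydrodynamic_radius_from_d(245.2497, env298), 1, tolerance = 1e-4)
  # R_H = kB*T/(6 pi eta D): doubling eta at fixed D halves the radius
  env2 <- physical_environment(298, 2 * 0.89)
  expect_equal(hydrodynamic_radius_from_d(100, env2),
               hydrodynamic_radius_from_d(100, env298) / 2)
  expect_error(hydrodynamic_radius_from_d(0, env298), "positive")
})

test_that("volume fraction conversion reproduces the Ficoll checkpoint", {
  expect_equal(round(volume_fraction(1.2, 5.1), 2), 0.40)
  expect_identical(volume_fraction(0, 5.1), 0)
  expect_equal(volume_fraction(0.6, 5.1), 0.2008, tolerance = 1e-3)
  # linear in concentration, cubic in radius
  expect_equal(volume_fraction(2.4, 5.1), 2 * volume_fraction(1.2, 5.1))
  expect_equal(volume_fraction(1, 2 * 3), 8 * volume_fraction(1, 3))
  # exact inverse
  expect_equal(concentration_from_volume_fraction(volume_fraction(1.2, 5.1), 5.1),
               1.2, tolerance = 1e-12)
  expect_error(volume_fraction(-1, 5.1), "non-negative")
})

test_that("occupied_fraction sums sphere volumes over the selected species", {
  L <- 30
  cfg <- configuration(L, c("a", "a", "b"), c(2, 2, 3),
                       rbind(c(5, 5, 5), c(15, 15, 15), c(25, 25, 25)))
  expect_identical(occupied_fraction(cfg, character(0)), 0)
  expect_equal(occupied_fraction(cfg, "b"), (4 / 3) * pi * 27 / L^3)
  # additivity over disjoint subsets
  expect_equal(occupied_fraction(cfg, c("a", "b")),
               occupied_fraction(cfg, "a") + occupied_fraction(cfg, "b"))
  expect_equal(occupied_fraction(cfg), occupied_fraction(cfg, c("a", "b")))
  expect_error(occupied_fraction(cfg, "zzz"), "unknown")
})

test_that("configuration validates box size and overlaps", {
  expect_error(configuration(7, c("a", "a"), c(2, 2), rbind(c(1, 1, 1), c(5, 5, 5))),
               "exceed")
  expect_error(configuration(30, c("a", "a"), c(2, 2),
                             rbind(c(1, 1, 1), c(2, 2, 2))),
               "overlap")
})

test_that("species table round-trips through CSV and supports concentrations", {
  tab <- rbind(species("crowder", 5.1, 100), species("tracer", 0.8, 50))
  path <- withr::local_tempfile(fileext = ".csv")
  write_species_table(tab, path)
  expect_equal(read_species_table(path), tab)
  # concentration variant: 1.2 mM in an L-box must recover phi ~ 0.40
  path2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("label,radius_nm,concentration_mM", "crowder,5.1,1.2"), path2)
  tab2 <- read_species_table(path2, box_edge = 60)
  phi <- tab2$count * (4 / 3) * pi * 5.1^3 / 60^3
  expect_equal(phi, 0.40, tolerance = 0.01)
})

test_that("configurations round-trip through extended XYZ", {
  cfg <- build_mixture(species("crowder", 5.1, 20),
                       species("tracer", 0.8, 10), 0.05, seed = 42)
  path <- withr::local_tempfile(fileext = ".xyz")
  write_xyz(cfg, path, comment = c(seed = 42))
  back <- read_xyz(path)
  expect_equal(back$box_edge, cfg$box_edge)
  expect_equal(back$labels, cfg$labels)
  expect_equal(back$radii, cfg$radii)
  expect_equal(back$positions, cfg$positions, tolerance = 1e-9)
})
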