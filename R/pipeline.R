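# Experiment orchestration: build -> simulate -> analyze -> fit, driven by a
# JSON config, with seeded reproducibility and provenance logging. The
# experiments mirror the study design: a phi sweep at fixed tracer size, a
# size sweep of the slowdown parameter kappa, an excluded-volume comparison,
# a polydisperse cytoplasm run, and a standalone nanoviscosity curve fit.

#' Simulate one crowded state point and return D/D0 of the tracers
#'
#' Builds a crowder/tracer mixture at occupancy `phi`, runs Brownian
#' dynamics, and extracts the tracers' long-time diffusion coefficient
#' relative to the dilute (SSE) value. At `phi = 0` the run contains tracers
#' only (the free-diffusion control); at `r_h = r_c` (self-crowding) the
#' crowders themselves are tracked instead of adding same-size tracers.
#'
#' @param r_h Tracer radius, nm.
#' @param phi Crowder occupied volume fraction (decimal).
#' @param r_c Crowder radius, nm (default 5.1, a Ficoll70-like sphere).
#' @param n_crowders Crowder count at `phi > 0` (box edge derived).
#' @param n_tracers Tracer count (default 50).
#' @param n_steps,sampling_interval,n_equil Propagation control, see
#'   [bd_params()].
#' @param seed Integer seed.
#' @param env A [physical_environment()].
#' @param box_edge_phi0 Box edge used for the `phi = 0` control, nm.
#' @param n_replicates Independent configurations built, propagated and
#'   averaged (inverse-variance) per state point; replicate scatter feeds the
#'   combined SE. Averaging over distinct configurations is the standard way
#'   to beat down configuration-level fluctuations at fixed run length.
#' @return List: `d_ratio`, `sigma` (propagated SE), `d` (nm^2/us), `d0`,
#'   `msd`, `trajectory` metadata.
#' @export
simulate_state_point <- function(r_h, phi, r_c = 5.1, n_crowders = 100,
                                 n_tracers = 50, n_steps = 1e5,
                                 sampling_interval = max(1, round(n_steps / 1000)),
                                 n_equil = round(0.1 * n_steps), seed = 1,
                                 env = physical_environment(),
                                 box_edge_phi0 = 60, n_replicates = 1) {
  if (n_replicates > 1) {
    reps <- lapply(seq_len(n_replicates), function(r)
      simulate_state_point(r_h, phi, r_c = r_c, n_crowders = n_crowders,
                           n_tracers = n_tracers, n_steps = n_steps,
                           sampling_interval = sampling_interval,
                           n_equil = n_equil, seed = seed + 7919L * r,
                           env = env, box_edge_phi0 = box_edge_phi0,
                           n_replicates = 1))
    w <- vapply(reps, function(p) 1 / max(p$se, 1e-12)^2, numeric(1))
    d <- sum(w * vapply(reps, `[[`, numeric(1), "d")) / sum(w)
    se <- sqrt(1 / sum(w))
    d0 <- reps[[1]]$d0
    return(list(d_ratio = d / d0, sigma = se / d0, d = d, se = se, d0 = d0,
                msd = reps[[1]]$msd,
                local_exponent = min(vapply(reps, `[[`, numeric(1),
                                            "local_exponent")),
                phi = phi, r_h = r_h, seed = seed,
                n_particles = reps[[1]]$n_particles,
                n_replicates = n_replicates))
  }
  self_crowding <- abs(r_h - r_c) < 1e-9
  if (phi <= 0) {
    cfg <- build_mixture(species("crowder", r_c, 0),
                         species("tracer", r_h, n_tracers),
                         target_phi_occ = 0, box_edge = box_edge_phi0,
                         seed = seed)
    watch <- "tracer"
  } else if (self_crowding) {
    cfg <- build_mixture(species("crowder", r_c, n_crowders),
                         tracers = NULL, target_phi_occ = phi, seed = seed)
    watch <- "crowder"
  } else {
    cfg <- build_mixture(species("crowder", r_c, n_crowders),
                         species("tracer", r_h, n_tracers),
                         target_phi_occ = phi, seed = seed)
    watch <- "tracer"
  }
  params <- bd_params(n_steps = n_steps, sampling_interval = sampling_interval,
                      seed = seed + 1000L, env = env, n_equil = n_equil)
  traj <- run_trajectory(cfg, params)
  # a short lag window (3-10% of the span) keeps the estimator variance low
  # while staying beyond the crossover to the diffusive regime
  msd <- compute_msd(traj, species = watch, max_lag_fraction = 0.1)
  est <- long_time_d(msd)
  d0 <- sse_diffusivity(r_h, env)
  list(d_ratio = est$d / d0, sigma = est$se / d0, d = est$d, se = est$se,
       d0 = d0, msd = msd, local_exponent = est$local_exponent,
       phi = phi, r_h = r_h, seed = seed, n_particles = length(cfg$radii),
       n_replicates = 1)
}

#' Phi sweep: slowdown curve and kappa at fixed tracer size
#'
#' Runs [simulate_state_point()] across a phi grid (which must include 0)
#' and fits the linear slowdown law for kappa.
#'
#' @inheritParams simulate_state_point
#' @param phi_grid Occupied-fraction grid including 0.
#' @param ... Passed to [simulate_state_point()].
#' @return List: `curve` ([slowdown_curve()]), `kappa_fit`, `points`.
#' @export
run_phi_sweep <- function(r_h, phi_grid = c(0, 0.1, 0.2, 0.3), seed = 1, ...) {
  if (!any(phi_grid == 0)) stop("phi_grid must include the phi = 0 control")
  pts <- lapply(seq_along(phi_grid), function(i)
    simulate_state_point(r_h, phi_grid[i], seed = seed + i, ...))
  d_ratio <- vapply(pts, `[[`, numeric(1), "d_ratio")
  sigma <- vapply(pts, `[[`, numeric(1), "sigma")
  # the phi = 0 control calibrates D0; its ratio is forced to the anchor
  d_ratio[phi_grid == 0] <- 1
  curve <- slowdown_curve(phi_grid, pmin(d_ratio, 1.05),
                          sigma = pmax(sigma, 1e-12))
  list(curve = curve, kappa_fit = fit_kappa(curve), points = pts)
}

#' Size sweep: kappa(R_H) across tracer radii
#'
#' @param r_h_grid Tracer radii, nm.
#' @param phi_grid Passed to [run_phi_sweep()].
#' @param n_steps_for Optional function of `r_h` giving per-size step counts
#'   (smaller tracers need more, shorter steps); default scales inversely
#'   with `r_h` from `n_steps_ref` at 0.8 nm.
#' @param n_steps_ref Step count at the 0.8 nm reference size.
#' @param seed Integer seed.
#' @param ... Passed to [simulate_state_point()].
#' @return List: `kappa_table` (data frame r_h_nm, kappa, kappa_se,
#'   r_squared), `sweeps` (per-size phi-sweep results).
#' @export
run_size_sweep <- function(r_h_grid = c(0.8, 2.5, 5.1),
                           phi_grid = c(0, 0.1, 0.2, 0.3),
                           n_steps_for = NULL, n_steps_ref = 1e5, seed = 1,
                           ...) {
  # required steps scale as 1/r_h^2: the physical time to diffuse a fixed
  # length grows like r_h while the stable dt grows like r_h^3
  if (is.null(n_steps_for))
    n_steps_for <- function(r_h) max(2e4L, round(n_steps_ref * (0.8 / r_h)^2))
  sweeps <- lapply(seq_along(r_h_grid), function(i)
    run_phi_sweep(r_h_grid[i], phi_grid = phi_grid,
                  n_steps = n_steps_for(r_h_grid[i]),
                  seed = seed + 100L * i, ...))
  kappa_table <- data.frame(
    r_h_nm = r_h_grid,
    kappa = vapply(sweeps, function(s) s$kappa_fit$kappa, numeric(1)),
    kappa_se = vapply(sweeps, function(s) s$kappa_fit$kappa_se, numeric(1)),
    r_squared = vapply(sweeps, function(s) s$kappa_fit$r_squared, numeric(1)))
  list(kappa_table = kappa_table, sweeps = sweeps)
}

#' Excluded-volume comparison table
#'
#' For each tracer radius: the Monte-Carlo excluded-volume fraction over
#' crowder configurations (sampled from a short BD run, or static packings),
#' the cubic and linear closed forms, and the Maxwell-Garnett D/D0 from the
#' MC estimate.
#'
#' @param r_h_grid Tracer radii, nm.
#' @param phi Crowder occupied fraction.
#' @param r_c Crowder radius, nm.
#' @param n_crowders Crowders per configuration.
#' @param n_configs Number of configurations averaged (default 5).
#' @param n_insertions MC insertions per configuration.
#' @param config_mode `"bd"` (sample configurations from a BD run after
#'   equilibration) or `"static"` (independent random packings; faster).
#' @param n_steps BD steps between sampled configurations in `"bd"` mode.
#' @param seed Integer seed.
#' @param env A [physical_environment()].
#' @return Data frame: r_h_nm, phi_ex_mc, phi_ex_se, phi_ex_cubic,
#'   phi_ex_linear, d_ratio_mg.
#' @export
run_phiex_compare <- function(r_h_grid, phi = 0.1, r_c = 5.1,
                              n_crowders = 100, n_configs = 5,
                              n_insertions = 1e5,
                              config_mode = c("bd", "static"), n_steps = 2000,
                              seed = 1, env = physical_environment()) {
  config_mode <- match.arg(config_mode)
  configs <- if (config_mode == "static") {
    lapply(seq_len(n_configs), function(k)
      build_mixture(species("crowder", r_c, n_crowders), NULL,
                    target_phi_occ = phi, seed = seed + k))
  } else {
    cfg <- build_mixture(species("crowder", r_c, n_crowders), NULL,
                         target_phi_occ = phi, seed = seed)
    params <- bd_params(n_steps = n_configs * n_steps,
                        sampling_interval = n_steps, seed = seed + 1000L,
                        env = env)
    traj <- run_trajectory(cfg, params)
    nf <- length(traj$times)
    lapply(seq(nf - n_configs + 1, nf), function(f) trajectory_frame(traj, f))
  }
  rows <- lapply(r_h_grid, function(r_h) {
    mc <- phi_ex_mc(configs, r_h, n_insertions = n_insertions,
                    seed = seed + 7L)
    data.frame(r_h_nm = r_h, phi_ex_mc = mc$phi_ex, phi_ex_se = mc$se,
               phi_ex_cubic = phi_ex_cubic(phi, r_h, r_c),
               phi_ex_linear = phi_ex_linear(phi, r_h, r_c),
               d_ratio_mg = mg_diffusivity(min(mc$phi_ex, 1)))
  })
  out <- do.call(rbind, rows)
  attr(out, "phi_occ") <- phi
  attr(out, "configs") <- length(configs)
  out
}

#' Cytoplasm run: size-dependent slowdown under polydisperse crowding
#'
#' Builds the cytoplasm-like configuration, runs BD, and reports D/D0 per
#' species against its radius, optionally fitting the nanoviscosity model.
#'
#' @param composition Species table (default: packaged synthetic stand-in).
#' @param target_phi_occ Macromolecular occupancy (default 0.426).
#' @param metabolite Tracer [species()] row (default: 50 x 0.8 nm).
#' @param count_scale Composition count multiplier (see [build_cytoplasm()]).
#' @param n_steps,sampling_interval BD control.
#' @param seed Integer seed.
#' @param env A [physical_environment()].
#' @param fit Fit the nanoviscosity model to the resulting curve when
#'   `TRUE`, in the minimal-length mode (`fix_a`, fitting b, r_c_eff and
#'   r_min): with metabolite-sized points present the plain model's
#'   vanishing small-size slowdown cannot hold, and the free exponent is
#'   poorly identified on curves that stop at ribosome size.
#' @param fix_a Exponent used for the fit (default 1).
#' @return List: `curve` (per-species r_h_nm, d_ratio, sigma),
#'   `config` summary, optional `nanovisc_fit`.
#' @export
run_cytoplasm <- function(composition = default_cytoplasm_composition(),
                          target_phi_occ = 0.426,
                          metabolite = species("metabolite", 0.8, 50),
                          count_scale = 1, n_steps = 2e4,
                          sampling_interval = 50, seed = 1,
                          env = physical_environment(), fit = FALSE,
                          fix_a = 1) {
  cfg <- build_cytoplasm(composition, metabolite, target_phi_occ,
                         seed = seed, count_scale = count_scale)
  params <- bd_params(n_steps = n_steps, sampling_interval = sampling_interval,
                      seed = seed + 1000L, env = env,
                      n_equil = round(0.1 * n_steps))
  traj <- run_trajectory(cfg, params)
  labs <- unique(cfg$labels)
  rows <- lapply(labs, function(lbl) {
    r <- cfg$radii[match(lbl, cfg$labels)]
    est <- long_time_d(compute_msd(traj, species = lbl))
    d0 <- sse_diffusivity(r, env)
    data.frame(label = lbl, r_h_nm = r, d_ratio = est$d / d0,
               sigma = est$se / d0)
  })
  curve <- do.call(rbind, rows)
  curve <- curve[order(curve$r_h_nm), ]
  out <- list(curve = curve,
              phi_occ = attr(cfg, "phi_occ_macromolecules"),
              n_particles = length(cfg$radii), seed = seed)
  if (fit) {
    sc <- slowdown_curve(abscissa = curve$r_h_nm,
                         d_ratio = pmin(curve$d_ratio, 1.05),
                         sigma = pmax(curve$sigma, 1e-6),
                         abscissa_name = "r_h_nm")
    out$nanovisc_fit <- fit_nanovisc(sc, phi_occ = out$phi_occ, fix_a = fix_a)
  }
  out
}

#' Run a configured experiment
#'
#' Dispatches on `config$experiment` (`phi_sweep`, `size_sweep`,
#' `phiex_compare`, `cytoplasm`, or `nanovisc_fit`), executes the
#' build -> simulate -> analyze -> fit chain, and writes curves (CSV), fits
#' (JSON) and a provenance log to `config$out_dir`. Every output file carries
#' the config hash; reruns with the same config produce identical payloads.
#'
#' @param config Path to a JSON config file, or an equivalent named list.
#'   Required fields: `experiment`, `seed`, `out_dir`; the rest are
#'   experiment parameters passed through to the corresponding `run_*`
#'   function (grids, counts, step numbers, `composition_path`,
#'   `curve_path`, `phi_occ`, `fix_a`, ...).
#' @return The experiment result, invisibly, with attribute `files`.
#' @export
run_experiment <- function(config) {
  if (is.character(config)) config <- jsonlite::read_json(config,
                                                          simplifyVector = TRUE)
  for (f in c("experiment", "seed", "out_dir"))
    if (is.null(config[[f]])) stop("config lacks required field '", f, "'")
  experiment <- match.arg(config$experiment,
                          c("phi_sweep", "size_sweep", "phiex_compare",
                            "cytoplasm", "nanovisc_fit"))
  out_dir <- config$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  hash <- .config_hash(config)
  seed <- as.integer(config$seed)
  env <- physical_environment(config$temperature %||% 298,
                              config$viscosity %||% 0.89)
  t0 <- proc.time()[["elapsed"]]
  files <- character(0)
  put <- function(name) { p <- file.path(out_dir, name); files <<- c(files, p); p }

  result <- switch(experiment,
    phi_sweep = {
      res <- run_phi_sweep(r_h = config$r_h %||% 0.8,
                           phi_grid = config$phi_grid %||% c(0, 0.1, 0.2, 0.3),
                           seed = seed,
                           r_c = config$r_c %||% 5.1,
                           n_crowders = config$n_crowders %||% 100,
                           n_tracers = config$n_tracers %||% 50,
                           n_steps = config$n_steps %||% 1e5,
                           n_replicates = config$n_replicates %||% 1,
                           box_edge_phi0 = config$box_edge_phi0 %||% 60,
                           env = env)
      write_curve_csv(res$curve, put("slowdown_curve.csv"),
                      comment = paste0("config_hash=", hash))
      .write_json(c(res$kappa_fit[c("kappa", "kappa_se", "r_squared",
                                    "n_points")],
                    list(config_hash = hash)), put("kappa_fit.json"))
      res
    },
    size_sweep = {
      res <- run_size_sweep(r_h_grid = config$r_h_grid %||% c(0.8, 2.5, 5.1),
                            phi_grid = config$phi_grid %||% c(0, 0.1, 0.2, 0.3),
                            n_steps_ref = config$n_steps_ref %||% 1e5,
                            seed = seed,
                            r_c = config$r_c %||% 5.1,
                            n_crowders = config$n_crowders %||% 100,
                            n_tracers = config$n_tracers %||% 50,
                            env = env)
      write_curve_csv(res$kappa_table, put("kappa_vs_rh.csv"),
                      comment = paste0("config_hash=", hash))
      res
    },
    phiex_compare = {
      res <- run_phiex_compare(r_h_grid = config$r_h_grid %||%
                                 c(0, 0.8, 2.5, 5.1),
                               phi = config$phi %||% 0.1,
                               r_c = config$r_c %||% 5.1,
                               n_crowders = config$n_crowders %||% 100,
                               n_configs = config$n_configs %||% 5,
                               n_insertions = config$n_insertions %||% 1e5,
                               config_mode = config$config_mode %||% "bd",
                               seed = seed, env = env)
      write_curve_csv(res, put("phiex_compare.csv"),
                      comment = paste0("config_hash=", hash))
      res
    },
    cytoplasm = {
      comp <- if (!is.null(config$composition_path))
        read_species_table(config$composition_path)
      else default_cytoplasm_composition()
      res <- run_cytoplasm(composition = comp,
                           target_phi_occ = config$target_phi_occ %||% 0.426,
                           metabolite = species(
                             "metabolite", config$metabolite_radius %||% 0.8,
                             config$n_metabolites %||% 50),
                           count_scale = config$count_scale %||% 1,
                           n_steps = config$n_steps %||% 2e4,
                           sampling_interval = config$sampling_interval %||% 50,
                           seed = seed, env = env,
                           fit = isTRUE(config$fit),
                           fix_a = config$fix_a %||% 1)
      write_curve_csv(res$curve, put("cytoplasm_slowdown.csv"),
                      comment = paste0("config_hash=", hash))
      if (!is.null(res$nanovisc_fit))
        .write_json(c(unclass(res$nanovisc_fit$params)[c("a", "b", "r_c_eff",
                                                         "r_min", "xi")],
                      list(config_hash = hash)), put("nanovisc_fit.json"))
      res
    },
    nanovisc_fit = {
      if (is.null(config$curve_path) || is.null(config$phi_occ))
        stop("nanovisc_fit needs curve_path and phi_occ")
      curve <- read_curve_csv(config$curve_path)
      res <- fit_nanovisc(curve, phi_occ = config$phi_occ,
                          fix_a = config$fix_a)
      .write_json(c(unclass(res$params)[c("a", "b", "r_c_eff", "r_min",
                                          "xi")],
                    list(residual_norm = res$residual_norm,
                         config_hash = hash)), put("nanovisc_fit.json"))
      res
    })

  log <- list(experiment = experiment, config = config, config_hash = hash,
              seed = seed, package_version = as.character(
                packageVersion("crowdiff")),
              elapsed_s = proc.time()[["elapsed"]] - t0,
              files = basename(files))
  jsonlite::write_json(log, file.path(out_dir, "provenance.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  attr(result, "files") <- files
  invisible(result)
}

# md5 of the canonical (sorted-key) JSON rendering of the config.
.config_hash <- function(config) {
  config$out_dir <- NULL  # payloads should not depend on where they land
  canon <- jsonlite::toJSON(config[order(names(config))], auto_unbox = TRUE,
                            digits = NA)
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(canon, tmp)
  unname(tools::md5sum(tmp))
}

.write_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}
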