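# Overdamped Brownian dynamics of hard spheres without hydrodynamic
# interactions: forward Euler free displacements followed by an elastic
# (Heyes-Melrose style) correction that moves every overlapping pair back to
# contact along the center line, split in proportion to the particles' dilute
# diffusivities. Iterated to convergence each step.

#' Brownian dynamics parameters
#'
#' @param timestep Timestep dt in us. `NULL` (default) chooses dt so that the
#'   RMS free displacement of the most mobile species is 5% of the smallest
#'   radius; the hard invariant (refused otherwise) is 10%.
#' @param n_steps Number of propagation steps.
#' @param sampling_interval Store a frame every this many steps.
#' @param seed Integer seed (single stream per run, recorded in outputs).
#' @param env A [physical_environment()] supplying T and eta for the
#'   per-species dilute diffusivities.
#' @param n_equil Leading steps flagged as equilibration; sampled frames in
#'   that segment are marked and skipped by default in MSD analysis.
#' @return An object of class `bd_params`.
#' @export
bd_params <- function(timestep = NULL, n_steps, sampling_interval = 100,
                      seed = 1, env = physical_environment(), n_equil = 0) {
  stopifnot(n_steps >= 0, sampling_interval >= 1, n_equil >= 0)
  structure(list(timestep = timestep, n_steps = as.integer(n_steps),
                 sampling_interval = as.integer(sampling_interval),
                 seed = as.integer(seed), env = env,
                 n_equil = as.integer(n_equil)),
            class = "bd_params")
}

# dt with RMS free step = frac * smallest radius for the fastest species.
.default_dt <- function(radii, env, frac = 0.05) {
  r_min <- min(radii)
  d_max <- sse_diffusivity(r_min, env)
  (frac * r_min)^2 / (2 * d_max)
}

.check_dt <- function(dt, radii, env) {
  r_min <- min(radii)
  d_max <- max(sse_diffusivity(radii, env))
  if (sqrt(2 * d_max * dt) > 0.1 * r_min)
    stop("timestep too large: RMS free displacement sqrt(2*D0*dt) exceeds ",
         "10% of the smallest radius")
  dt
}

#' One forward-Euler Brownian step
#'
#' Displaces every particle by an independent Gaussian vector with per-axis
#' variance `2*D0(species)*dt`, then resolves hard-core overlaps. Exposed
#' mainly for testing; production runs use [run_trajectory()].
#'
#' @param config An overlap-free [configuration()].
#' @param params A [bd_params()]. The RNG is the global R stream; call
#'   `set.seed()` for reproducibility.
#' @return The propagated [configuration()].
#' @export
euler_step <- function(config, params) {
  stopifnot(inherits(config, "configuration"), inherits(params, "bd_params"))
  d0 <- sse_diffusivity(config$radii, params$env)
  dt <- params$timestep
  if (is.null(dt)) dt <- .default_dt(config$radii, params$env)
  .check_dt(dt, config$radii, params$env)
  res <- cpp_bd_run(config$positions, config$radii, d0, config$box_edge,
                    dt, 1L, 1L, 100L)
  configuration(config$box_edge, config$labels, config$radii,
                res$final_wrapped)
}

#' Resolve hard-core overlaps in a configuration
#'
#' Every overlapping pair is moved apart along the center line exactly to
#' contact, with the displacement shared in proportion to each particle's
#' dilute diffusivity D0 (i.e. its mobility); sweeps repeat until no overlap
#' remains. Overlap-free input is returned unchanged.
#'
#' @param config A [configuration()] (overlaps permitted on input, so the
#'   constructor check is bypassed internally).
#' @param env A [physical_environment()] for the D0 weights.
#' @param max_sweeps Error out after this many sweeps without convergence
#'   (signals too-large dt or phi).
#' @return Overlap-free [configuration()] with attribute `sweeps`.
#' @export
resolve_overlaps <- function(config, env = physical_environment(),
                             max_sweeps = 100) {
  stopifnot(inherits(config, "configuration"))
  d0 <- sse_diffusivity(config$radii, env)
  res <- cpp_resolve_overlaps(config$positions, config$radii, d0,
                              config$box_edge, max_sweeps)
  if (!isTRUE(res$converged))
    stop("overlap resolution did not converge in ", max_sweeps,
         " sweeps (too-large dt or phi_occ)")
  out <- config
  if (res$sweeps > 0) out$positions <- res$positions
  attr(out, "sweeps") <- res$sweeps
  out
}

#' Run a Brownian dynamics trajectory
#'
#' Propagates `params$n_steps` Euler steps from `config`, storing unwrapped
#' positions every `params$sampling_interval` steps (plus the initial frame).
#' Deterministic given `params$seed`.
#'
#' @param config Overlap-free starting [configuration()].
#' @param params A [bd_params()].
#' @return An object of class `bd_trajectory`: times (us), per-particle
#'   labels/radii/D0, the unwrapped position array (frames x particles x 3),
#'   the final wrapped configuration, and an `equilibrated` flag per frame.
#' @export
run_trajectory <- function(config, params) {
  stopifnot(inherits(config, "configuration"), inherits(params, "bd_params"))
  if (min_pair_gap(config) < -1e-9) stop("starting configuration has overlaps")
  d0 <- sse_diffusivity(config$radii, params$env)
  dt <- params$timestep
  if (is.null(dt)) dt <- .default_dt(config$radii, params$env)
  .check_dt(dt, config$radii, params$env)
  set.seed(params$seed)
  res <- cpp_bd_run(config$positions, config$radii, d0, config$box_edge,
                    dt, params$n_steps, params$sampling_interval, 100L)
  times <- res$frame_steps * dt
  structure(list(times = times,
                 box_edge = config$box_edge,
                 labels = config$labels,
                 radii = config$radii,
                 d0 = d0,
                 timestep = dt,
                 seed = params$seed,
                 unwrapped = res$unwrapped,
                 final = configuration(config$box_edge, config$labels,
                                       config$radii, res$final_wrapped),
                 equilibrated = res$frame_steps >= params$n_equil),
            class = "bd_trajectory")
}

#' @export
print.bd_trajectory <- function(x, ...) {
  cat(sprintf("<bd_trajectory> %d frames, %d particles, dt = %.3g us, t = %.4g us\n",
              length(x$times), length(x$radii), x$timestep, max(x$times)))
  invisible(x)
}

#' Extract a frame of a trajectory as a configuration
#'
#' @param traj A `bd_trajectory`.
#' @param frame Frame index (1-based).
#' @return A [configuration()] (positions wrapped back into the box).
#' @export
trajectory_frame <- function(traj, frame) {
  stopifnot(inherits(traj, "bd_trajectory"))
  pos <- traj$unwrapped[frame, , , drop = TRUE]
  if (is.null(dim(pos))) pos <- matrix(pos, ncol = 3)
  configuration(traj$box_edge, traj$labels, traj$radii, pos %% traj$box_edge)
}
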