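# Synthetic pulsed-gradient stimulated-echo (PGSTE) NMR data: Stejskal-Tanner
# attenuation series with known ground truth and Gaussian noise, plus the
# nonlinear fit that recovers D from such series. Also the free-diffusion
# random-walk generator used to calibrate the MSD pipeline, and noisy
# slowdown-curve generators with recorded truth.

#' PGSTE acquisition parameters
#'
#' @param gamma Gyromagnetic ratio in rad s^-1 T^-1 (default: 1H,
#'   2.6752218744e8).
#' @param delta_ms Gradient pulse duration delta in ms (must be < Delta).
#' @param Delta_ms Diffusion delay Delta in ms.
#' @param gradients Gradient strengths g in T/m: at least 5 non-negative,
#'   strictly increasing values.
#' @return An object of class `pgste_acquisition`.
#' @examples
#' pgste_acquisition(delta_ms = 2, Delta_ms = 100,
#'                   gradients = seq(0, 0.5, length.out = 16))
#' @export
pgste_acquisition <- function(gamma = 2.6752218744e8, delta_ms = 2,
                              Delta_ms = 100,
                              gradients = seq(0, 0.5, length.out = 16)) {
  if (delta_ms >= Delta_ms) stop("delta must be smaller than Delta")
  if (length(gradients) < 5) stop("need at least 5 gradient values")
  if (any(gradients < 0)) stop("gradients must be non-negative")
  if (any(diff(gradients) <= 0)) stop("gradients must be strictly increasing")
  structure(list(gamma = gamma, delta_ms = delta_ms, Delta_ms = Delta_ms,
                 gradients = gradients),
            class = "pgste_acquisition")
}

# Stejskal-Tanner b-factor in s/m^2: gamma^2 g^2 delta^2 (Delta - delta/3).
.b_factor <- function(g, acq) {
  delta <- acq$delta_ms * 1e-3
  Delta <- acq$Delta_ms * 1e-3
  acq$gamma^2 * g^2 * delta^2 * (Delta - delta / 3)
}

#' Stejskal-Tanner attenuation
#'
#' Normalized echo attenuation `I/I0 = exp[-D * gamma^2 g^2 delta^2
#' (Delta - delta/3)]` for self-diffusion coefficient D under a pulsed
#' gradient pair.
#'
#' @param g Gradient strength(s) in T/m.
#' @param acq A [pgste_acquisition()].
#' @param d Diffusion coefficient in m^2/s (>= 0).
#' @return Attenuation factor(s) in (0, 1].
#' @export
stejskal_tanner <- function(g, acq, d) {
  stopifnot(inherits(acq, "pgste_acquisition"))
  if (d < 0) stop("d must be >= 0")
  exp(-d * .b_factor(g, acq))
}

#' Simulate a noisy PGSTE attenuation series
#'
#' Evaluates the Stejskal-Tanner model at every gradient of the acquisition
#' and adds independent additive Gaussian noise of standard deviation
#' `noise_sd` to the normalized intensities. The truth and seed are recorded
#' in the returned object.
#'
#' @param d_true True diffusion coefficient, m^2/s.
#' @param acq A [pgste_acquisition()].
#' @param noise_sd Noise standard deviation on I/I0 (>= 0).
#' @param seed Integer seed; same seed, same series.
#' @return An object of class `attenuation_series` with fields `acquisition`,
#'   `signal`, `noise_sd`, `d_true`, `seed`.
#' @export
simulate_series <- function(d_true, acq = pgste_acquisition(),
                            noise_sd = 0.01, seed = 1) {
  stopifnot(inherits(acq, "pgste_acquisition"))
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  set.seed(seed)
  model <- stejskal_tanner(acq$gradients, acq, d_true)
  signal <- model + rnorm(length(model), sd = noise_sd)
  structure(list(acquisition = acq, signal = signal, noise_sd = noise_sd,
                 d_true = d_true, seed = seed),
            class = "attenuation_series")
}

#' Fit a diffusion coefficient to an attenuation series
#'
#' Nonlinear least squares of `I = I0 * exp(-b(g) * D)` in `(I0, D)`,
#' initialized by the log-linear fit of the positive intensities. D is scaled
#' internally (units of 1e-10 m^2/s) for conditioning. The standard error is
#' read off the Jacobian-based covariance.
#'
#' @param series An `attenuation_series` (or a list with `acquisition` and
#'   `signal`).
#' @return List of class `attenuation_fit`: `d` (m^2/s), `se`, `i0`,
#'   `ci95` (Wald 95% interval on D).
#' @export
fit_attenuation <- function(series) {
  acq <- series$acquisition
  y <- series$signal
  if (length(y) < 5) stop("need at least 5 gradient points")
  b <- .b_factor(acq$gradients, acq)
  pos <- y > 0
  noise_tol <- max(3 * series$noise_sd %||% 0.05, 0.05)
  if (any(y < -noise_tol))
    stop("signals more negative than the noise tolerance; not an attenuation ",
         "series")
  if (sum(pos) < 3) stop("too few positive intensities to initialize the fit")
  # log-linear initialization: log I = log I0 - b * D
  init <- unname(coef(lm(log(y[pos]) ~ b[pos])))
  d0_scaled <- max(-init[2] / 1e-10, 1e-4)  # D in 1e-10 m^2/s
  bs <- b * 1e-10
  fit <- minpack.lm::nlsLM(y ~ i0 * exp(-bs * ds),
                           start = list(i0 = exp(init[1]), ds = d0_scaled),
                           lower = c(i0 = 0, ds = 0),
                           control = minpack.lm::nls.lm.control(maxiter = 200))
  cf <- coef(fit)
  vc <- vcov(fit)
  d_hat <- cf[["ds"]] * 1e-10
  se <- sqrt(vc["ds", "ds"]) * 1e-10
  structure(list(d = d_hat, se = se, i0 = cf[["i0"]],
                 ci95 = d_hat + c(-1, 1) * qnorm(0.975) * se),
            class = "attenuation_fit")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Generate a noisy slowdown curve with known truth
#'
#' Synthetic stand-ins for measured slowdown data: either the linear law
#' `D/D0 = 1 - kappa*phi_occ` sampled on a phi grid, or the nanoviscosity
#' model sampled on a log-spaced R_H grid. Gaussian noise is added to the
#' model values; the generating truth and seed are recorded as attributes
#' for recovery tests.
#'
#' @param kind `"linear_phi"` or `"nanovisc_rh"`.
#' @param truth For `"linear_phi"`: a list with `kappa` (and optionally
#'   `phi_max`, default 0.3). For `"nanovisc_rh"`: a [nanovisc_params()]
#'   (plus optional `r_h_range`, default 0.5-13 nm).
#' @param n_points Number of abscissa points.
#' @param noise_sd Gaussian noise sd on D/D0.
#' @param seed Integer seed.
#' @return A [slowdown_curve()] with attributes `truth`, `kind`, `seed`.
#' @export
generate_slowdown_table <- function(kind = c("linear_phi", "nanovisc_rh"),
                                    truth, n_points = 8, noise_sd = 0.01,
                                    seed = 1) {
  kind <- match.arg(kind)
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  set.seed(seed)
  if (kind == "linear_phi") {
    if (is.null(truth$kappa)) stop("truth$kappa is required for linear_phi")
    phi_max <- truth$phi_max %||% 0.3
    phi <- seq(0, phi_max, length.out = n_points)
    model <- 1 - truth$kappa * phi
    if (any(model <= 0))
      stop("kappa*phi_max >= 1: model crosses zero on this grid")
    y <- model + rnorm(n_points, sd = noise_sd)
    y[phi == 0] <- model[phi == 0]  # the anchor is exact by construction
    y <- pmin(pmax(y, 1e-6), 1.05)
    out <- slowdown_curve(phi, y, sigma = rep(max(noise_sd, 1e-12), n_points),
                          abscissa_name = "phi_occ")
  } else {
    if (!inherits(truth, "nanovisc_params") &&
        !inherits(truth$params, "nanovisc_params"))
      stop("truth must carry nanovisc_params for nanovisc_rh")
    params <- if (inherits(truth, "nanovisc_params")) truth else truth$params
    rng <- if (!inherits(truth, "nanovisc_params"))
      truth$r_h_range %||% c(0.5, 13) else c(0.5, 13)
    r_h <- exp(seq(log(rng[1]), log(rng[2]), length.out = n_points))
    model <- d_ratio_nanovisc(r_h, params)
    y <- model + rnorm(n_points, sd = noise_sd)
    y <- pmin(pmax(y, 1e-6), 1.05)
    out <- slowdown_curve(r_h, y, sigma = rep(max(noise_sd, 1e-12), n_points),
                          abscissa_name = "r_h_nm")
  }
  attr(out, "truth") <- truth
  attr(out, "kind") <- kind
  attr(out, "seed") <- seed
  out
}

#' Generate a free-diffusion random walk
#'
#' Single-particle Gaussian random walk of known diffusivity, unwrapped, in
#' the trajectory container used by [compute_msd()]. Its MSD obeys
#' `6 * D * t` exactly in expectation, making it the calibration input for
#' the diffusivity pipeline.
#'
#' @param d_true Diffusion coefficient, nm^2/us.
#' @param n_steps Number of steps.
#' @param dt Timestep, us.
#' @param seed Integer seed.
#' @param n_particles Number of independent walkers (default 1).
#' @return A `bd_trajectory` with attribute `d_true`.
#' @export
generate_free_walk <- function(d_true, n_steps, dt, seed = 1,
                               n_particles = 1) {
  if (d_true <= 0 || n_steps <= 0 || dt <= 0)
    stop("d_true, n_steps and dt must all be positive")
  set.seed(seed)
  n_frames <- n_steps + 1
  arr <- array(0, dim = c(n_frames, n_particles, 3))
  sigma <- sqrt(2 * d_true * dt)
  for (i in seq_len(n_particles)) {
    steps <- matrix(rnorm(n_steps * 3, sd = sigma), n_steps, 3)
    arr[-1, i, ] <- apply(steps, 2, cumsum)
  }
  traj <- structure(list(times = (0:n_steps) * dt,
                         box_edge = Inf,
                         labels = rep("tracer", n_particles),
                         radii = rep(1, n_particles),
                         d0 = rep(d_true, n_particles),
                         timestep = dt,
                         seed = seed,
                         unwrapped = arr,
                         final = NULL,
                         equilibrated = rep(TRUE, n_frames)),
                    class = "bd_trajectory")
  attr(traj, "d_true") <- d_true
  traj
}
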