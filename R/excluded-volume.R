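# Excluded-volume fraction phi_ex: the volume inaccessible to the center of a
# finite tracer (crowders effectively enlarged by R_H), estimated by
# Monte-Carlo insertion or by closed-form approximations, and the
# Maxwell-Garnett point-tracer mapping to a relative diffusivity.

#' Monte-Carlo excluded-volume fraction
#'
#' Fraction of uniformly random insertion points of a tracer of radius
#' `tracer_radius` that overlap any crowder (minimum-image convention),
#' averaged over configurations, with the standard error computed over
#' configurations when two or more are supplied.
#'
#' @param configs A [configuration()] or list of configurations containing
#'   only crowders (exclude tracer particles before calling).
#' @param tracer_radius Tracer radius in nm (0 gives the point-tracer limit
#'   phi_ex -> phi_occ).
#' @param n_insertions Insertions per configuration (default 1e6; fewer than
#'   1e3 triggers a warning).
#' @param seed Integer seed; estimates are bitwise reproducible.
#' @return List of class `phi_ex_estimate`: `phi_ex`, `se`, `n_insertions`,
#'   `n_configs`, `per_config`.
#' @export
phi_ex_mc <- function(configs, tracer_radius, n_insertions = 1e6, seed = 1) {
  if (inherits(configs, "configuration")) configs <- list(configs)
  if (length(configs) == 0) stop("empty configuration list")
  if (tracer_radius < 0) stop("tracer_radius must be >= 0")
  if (n_insertions < 1e3)
    warning("fewer than 1000 insertions: estimate will be noisy")
  set.seed(seed)
  per_config <- vapply(configs, function(cfg) {
    stopifnot(inherits(cfg, "configuration"))
    cpp_phi_ex(cfg$positions, cfg$radii, cfg$box_edge, tracer_radius,
               as.integer(n_insertions))
  }, numeric(1))
  est <- mean(per_config)
  se <- if (length(per_config) >= 2)
    sd(per_config) / sqrt(length(per_config))
  else sqrt(est * (1 - est) / n_insertions)  # binomial SE, single config
  structure(list(phi_ex = est, se = se, n_insertions = as.integer(n_insertions),
                 n_configs = length(per_config), per_config = per_config),
            class = "phi_ex_estimate")
}

#' Cubic excluded-volume approximation
#'
#' Sums the exclusion spheres of radius `R_c + R_H` generated by all
#' crowders, neglecting their overlaps (valid only at low phi_occ):
#' `phi_ex = phi_occ * (1 + R_H/R_c)^3`.
#'
#' @param phi_occ Occupied volume fraction (decimal).
#' @param r_h Tracer radius, nm.
#' @param r_c Crowder radius, nm.
#' @return Excluded-volume fraction (may exceed 1 where the approximation
#'   breaks down).
#' @export
phi_ex_cubic <- function(phi_occ, r_h, r_c) {
  .check_phiex_args(phi_occ, r_h, r_c)
  phi_occ * (1 + r_h / r_c)^3
}

#' Linear excluded-volume approximation
#'
#' First order in `R_H/R_c`: `phi_ex = phi_occ * (1 + 3*R_H/R_c)`.
#'
#' @inheritParams phi_ex_cubic
#' @return Excluded-volume fraction.
#' @export
phi_ex_linear <- function(phi_occ, r_h, r_c) {
  .check_phiex_args(phi_occ, r_h, r_c)
  phi_occ * (1 + 3 * r_h / r_c)
}

.check_phiex_args <- function(phi_occ, r_h, r_c) {
  if (any(phi_occ < 0) || any(r_h < 0)) stop("phi_occ and r_h must be >= 0")
  if (any(r_c <= 0)) stop("r_c must be positive")
  invisible(TRUE)
}

#' Maxwell-Garnett relative diffusivity of a point tracer
#'
#' Effective-medium slowdown for transport around impermeable inclusions in
#' its linear point-tracer form, `D/D0 = 1 - phi_ex/2` (the kappa = 1/2 case
#' of the linear slowdown law). Finite tracer sizes are handled by passing an
#' excluded-volume fraction for `phi_ex`.
#'
#' @param phi_ex Excluded (or, for a point tracer, occupied) volume fraction,
#'   in `[0, 1]`.
#' @return D/D0.
#' @examples
#' mg_diffusivity(0.10)  # 0.95
#' @export
mg_diffusivity <- function(phi_ex) {
  if (any(phi_ex < 0) || any(phi_ex > 1))
    stop("phi_ex must lie in [0, 1]")
  1 - phi_ex / 2
}

#' Slowdown parameter from the linear excluded-volume theory
#'
#' Composing the Maxwell-Garnett point-tracer form with the linear
#' excluded-volume approximation gives the size-dependent slowdown
#' `kappa(R_H) = 0.5 * (1 + 3*R_H/R_c)`; self-crowding (`R_H = R_c`)
#' predicts kappa = 2 and a point tracer kappa = 1/2.
#'
#' @param r_h Tracer radius, nm (>= 0).
#' @param r_c Crowder radius, nm (> 0).
#' @return kappa (dimensionless).
#' @examples
#' kappa_linear_theory(5.1, 5.1)  # 2
#' @export
kappa_linear_theory <- function(r_h, r_c) {
  .check_phiex_args(0, r_h, r_c)
  0.5 * (1 + 3 * r_h / r_c)
}
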