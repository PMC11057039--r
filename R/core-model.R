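# Internal unit system: lengths in nm, times in microseconds, temperature in K,
# viscosity in mPa*s. Diffusivities are then nm^2/us (1 nm^2/us = 1e-12 m^2/s),
# which keeps Brownian step sizes of order 1e-3..1e-1 nm and avoids exponent
# underflow in long products.

#' Physical constants (CODATA)
#'
#' Boltzmann constant and Avogadro number at full published precision.
#' @name constants
#' @keywords internal
NULL

.kB <- 1.380649e-23       # J/K (exact, CODATA 2019)
.NAvogadro <- 6.02214076e23  # 1/mol (exact, CODATA 2019)

#' Physical environment for diffusion calculations
#'
#' Bundles absolute temperature and solvent viscosity. The default viscosity
#' (0.89 mPa*s) is water at 298 K; it is a configuration choice, not a
#' measured property of any particular crowded sample.
#'
#' @param temperature Absolute temperature in K.
#' @param solvent_viscosity Solvent (dilute-limit) dynamic viscosity in mPa*s.
#' @return An object of class `physical_environment`.
#' @examples
#' env <- physical_environment()
#' sse_diffusivity(1, env)
#' @export
physical_environment <- function(temperature = 298, solvent_viscosity = 0.89) {
  if (!is.numeric(temperature) || length(temperature) != 1 || temperature <= 0)
    stop("temperature must be a single positive number (K)")
  if (!is.numeric(solvent_viscosity) || length(solvent_viscosity) != 1 ||
      solvent_viscosity <= 0)
    stop("solvent_viscosity must be a single positive number (mPa*s)")
  structure(list(temperature = temperature,
                 solvent_viscosity = solvent_viscosity,
                 boltzmann_constant = .kB),
            class = "physical_environment")
}

#' Stokes-Sutherland-Einstein diffusivity
#'
#' Dilute-limit translational diffusion coefficient of a sphere,
#' D = kB*T / (6*pi*eta*R_H), returned in nm^2/us.
#'
#' @param radius Hydrodynamic radius in nm (vectorized).
#' @param env A [physical_environment()].
#' @return Diffusivity in nm^2/us (1 nm^2/us = 1e-12 m^2/s).
#' @seealso [hydrodynamic_radius_from_d()] for the exact inverse.
#' @examples
#' sse_diffusivity(1, physical_environment(298, 0.89))  # ~245 nm^2/us
#' @export
sse_diffusivity <- function(radius, env = physical_environment()) {
  stopifnot(inherits(env, "physical_environment"))
  if (any(!is.finite(radius)) || any(radius <= 0))
    stop("radius must be positive (nm)")
  # kB*T [J] / (6 pi eta [mPa*s = 1e-3 Pa*s] R [nm = 1e-9 m]) -> m^2/s,
  # then 1 m^2/s = 1e12 nm^2/us.
  d_si <- .kB * env$temperature /
    (6 * pi * env$solvent_viscosity * 1e-3 * radius * 1e-9)
  d_si * 1e12
}

#' Hydrodynamic radius from a diffusivity
#'
#' Exact algebraic inverse of [sse_diffusivity()]: R_H = kB*T / (6*pi*eta*D).
#'
#' @param diffusivity Diffusion coefficient in nm^2/us (vectorized).
#' @param env A [physical_environment()].
#' @return Hydrodynamic radius in nm.
#' @export
hydrodynamic_radius_from_d <- function(diffusivity, env = physical_environment()) {
  stopifnot(inherits(env, "physical_environment"))
  if (any(!is.finite(diffusivity)) || any(diffusivity <= 0))
    stop("diffusivity must be positive (nm^2/us)")
  d_si <- diffusivity * 1e-12
  .kB * env$temperature / (6 * pi * env$solvent_viscosity * 1e-3 * d_si) * 1e9
}

#' Occupied volume fraction from a molar concentration
#'
#' phi_occ = c * N_A * (4/3) pi R^3 for hard spheres of radius R at molar
#' concentration c. Fractions are carried as decimals throughout the package;
#' rendering as percent happens only at I/O.
#'
#' @param concentration Concentration in mM (vectorized).
#' @param radius Sphere radius in nm.
#' @return Occupied volume fraction (decimal).
#' @examples
#' volume_fraction(1.2, 5.1)  # ~0.40, a 1.2 mM Ficoll70 solution
#' @export
volume_fraction <- function(concentration, radius) {
  if (any(!is.finite(concentration)) || any(concentration < 0))
    stop("concentration must be non-negative (mM)")
  if (any(!is.finite(radius)) || any(radius <= 0))
    stop("radius must be positive (nm)")
  # c [mM] = 1e-3 mol/L; 1 L = 1e24 nm^3 -> number density in 1/nm^3.
  rho <- concentration * 1e-3 * .NAvogadro / 1e24
  rho * (4 / 3) * pi * radius^3
}

#' Molar concentration from an occupied volume fraction
#'
#' Exact inverse of [volume_fraction()] at fixed radius.
#'
#' @param phi_occ Occupied volume fraction (decimal).
#' @param radius Sphere radius in nm.
#' @return Concentration in mM.
#' @export
concentration_from_volume_fraction <- function(phi_occ, radius) {
  if (any(!is.finite(phi_occ)) || any(phi_occ < 0))
    stop("phi_occ must be non-negative")
  if (any(!is.finite(radius)) || any(radius <= 0))
    stop("radius must be positive (nm)")
  phi_occ / ((4 / 3) * pi * radius^3) * 1e24 / .NAvogadro * 1e3
}
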