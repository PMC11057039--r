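# Length-scale dependent ("nano") viscosity: eta(R_H)/eta0 =
# exp[b (R_eff/xi)^a], equivalently D/D0 = exp[-b (R_eff/xi)^a], where xi is
# the intercrowder gap and R_eff interpolates between the tracer radius
# (small tracers) and the crowder radius (large tracers).

.phi_rcp <- 0.638  # random close packing of hard spheres

#' psi at random close packing
#'
#' The map `phi/(1-phi)` evaluated at the hard-sphere random close packing
#' fraction (0.638), approximately 1.76. A fixed constant of the hard-sphere
#' intercrowder-gap expression.
#'
#' @return `0.638/(1 - 0.638)`.
#' @export
psi_rcp <- function() .phi_rcp / (1 - .phi_rcp)

#' Hard-sphere intercrowder gap
#'
#' `xi = R_g * psi_rcp * (1 - phi_occ)/phi_occ`: the characteristic free gap
#' between crowders of gyration radius `R_g` at occupancy `phi_occ`. For hard
#' spheres the gyration radius is taken equal to the crowder radius.
#'
#' @param r_g Crowder gyration radius, nm.
#' @param phi_occ Occupied volume fraction, strictly inside (0, 1).
#' @return Gap in nm (equals `R_g` exactly at random close packing).
#' @export
xi_hard_sphere <- function(r_g, phi_occ) {
  if (any(phi_occ <= 0) || any(phi_occ >= 1))
    stop("phi_occ must lie strictly inside (0, 1)")
  if (any(r_g <= 0)) stop("r_g must be positive")
  r_g * psi_rcp() * (1 - phi_occ) / phi_occ
}

#' Effective hydrodynamic radius
#'
#' Quadrature interpolant `R_eff = R_H*R_c / sqrt(R_H^2 + R_c^2)`, which
#' approaches the tracer radius for small tracers and the crowder radius for
#' large ones. A harmonic-mean alternative (`R_H*R_c/(R_H + R_c)`, same
#' limits up to a factor absorbed in b) is selectable; the two limits, not
#' the interpolant, are the contract.
#'
#' @param r_h Tracer radius, nm (>= 0).
#' @param r_c Effective crowder radius, nm (> 0).
#' @param interpolant `"quadrature"` (default) or `"harmonic"`.
#' @return Effective radius in nm.
#' @export
r_eff_standard <- function(r_h, r_c,
                           interpolant = c("quadrature", "harmonic")) {
  interpolant <- match.arg(interpolant)
  if (any(r_h < 0) || any(r_c <= 0)) stop("need r_h >= 0 and r_c > 0")
  switch(interpolant,
         quadrature = r_h * r_c / sqrt(r_h^2 + r_c^2),
         harmonic = r_h * r_c / (r_h + r_c))
}

#' Effective radius with a minimal length
#'
#' Evaluates [r_eff_standard()] at `R_H + R_min`. The minimal length keeps
#' `R_eff` (and hence the slowdown) from vanishing in the point-tracer limit,
#' which restores the linear-in-phi slowdown law with kappa linear in R_H at
#' small sizes. `r_min = 0` reduces exactly to [r_eff_standard()].
#'
#' @inheritParams r_eff_standard
#' @param r_min Minimal length, nm (>= 0).
#' @return Effective radius in nm.
#' @export
r_eff_modified <- function(r_h, r_c, r_min = 0,
                           interpolant = c("quadrature", "harmonic")) {
  if (any(r_min < 0)) stop("r_min must be >= 0")
  r_eff_standard(r_h + r_min, r_c, match.arg(interpolant))
}

#' Nanoviscosity model parameters
#'
#' @param a Stretching exponent (> 0), order unity.
#' @param b Prefactor (>= 0), order unity.
#' @param r_c_eff Effective crowder radius, nm.
#' @param r_min Minimal length, nm; 0 disables the extension.
#' @param phi_occ Occupied volume fraction used to derive the gap `xi` from
#'   `r_g` when `xi` is not given directly.
#' @param r_g Crowder gyration radius (defaults to `r_c_eff`, the hard-sphere
#'   choice).
#' @param xi Intercrowder gap, nm; derived via [xi_hard_sphere()] when `NULL`.
#' @param interpolant Effective-radius interpolant, see [r_eff_standard()].
#' @param a_small,a_switch_width Optional step-like exponent: `a(R_H)`
#'   crosses over logistically (in log R_H, width `a_switch_width` decades)
#'   from `a_small` at small tracers to `a` at large ones, centered on
#'   `r_c_eff`. `a_small = NULL` (default) keeps the exponent constant.
#' @return List of class `nanovisc_params`.
#' @export
nanovisc_params <- function(a, b, r_c_eff, r_min = 0, phi_occ = NULL,
                            r_g = r_c_eff, xi = NULL,
                            interpolant = "quadrature",
                            a_small = NULL, a_switch_width = 0.5) {
  if (a <= 0) stop("a must be positive")
  if (b < 0) stop("b must be non-negative")
  if (r_c_eff <= 0) stop("r_c_eff must be positive")
  if (is.null(xi)) {
    if (is.null(phi_occ))
      stop("supply either xi directly or phi_occ to derive it")
    xi <- xi_hard_sphere(r_g, phi_occ)
  }
  structure(list(a = a, b = b, r_c_eff = r_c_eff, r_min = r_min,
                 r_g = r_g, xi = xi, psi_rcp = psi_rcp(),
                 interpolant = interpolant, a_small = a_small,
                 a_switch_width = a_switch_width),
            class = "nanovisc_params")
}

.a_of_rh <- function(r_h, p) {
  if (is.null(p$a_small)) return(rep(p$a, length(r_h)))
  # logistic switch in log10(R_H/r_c_eff): a_small below, a above
  s <- 1 / (1 + exp(-log10(pmax(r_h, 1e-12) / p$r_c_eff) / p$a_switch_width))
  p$a_small + (p$a - p$a_small) * s
}

#' Relative diffusivity from the nanoviscosity model
#'
#' `D/D0 = eta0/eta(R_H) = exp[-b * (R_eff/xi)^a]` with `R_eff` from
#' [r_eff_modified()].
#'
#' @param r_h Tracer radius, nm (vectorized).
#' @param params A [nanovisc_params()].
#' @return D/D0 values.
#' @export
d_ratio_nanovisc <- function(r_h, params) {
  stopifnot(inherits(params, "nanovisc_params"))
  reff <- r_eff_modified(r_h, params$r_c_eff, params$r_min,
                         params$interpolant)
  exp(-params$b * (reff / params$xi)^.a_of_rh(r_h, params))
}

#' Fit the nanoviscosity model to a size-dependent slowdown curve
#'
#' Nonlinear least squares of `D/D0 = exp[-b (R_eff/xi)^a]` over `(R_H,
#' D/D0)` data at a known occupancy, with `xi` tied to the fitted effective
#' crowder radius through the hard-sphere gap expression. Two modes: fit
#' `(a, b, r_c_eff)` with `r_min = 0` (the standard model), or fix `a`
#' (typically at 1) and fit `(b, r_c_eff, r_min)` (the minimal-length
#' extension). Multi-start initialization (log-spaced `b` and `r_c_eff`)
#' guards against the local minima this model is prone to.
#'
#' @param curve A [slowdown_curve()] over `r_h_nm` (columns `r_h_nm`,
#'   `d_ratio`, optional `sigma`).
#' @param phi_occ Occupied volume fraction of the crowded system the curve
#'   was measured in.
#' @param fix_a `NULL` (fit a) or a fixed exponent value.
#' @param fit_r_min Fit the minimal length (default: only when `a` is
#'   fixed).
#' @param weighted Weight by `1/sigma^2` when sigmas are present.
#' @param n_starts Number of multi-start initializations (default 8).
#' @param interpolant Passed to [r_eff_standard()].
#' @return List of class `nanovisc_fit`: `params` ([nanovisc_params()]),
#'   `se` (named SEs from the Jacobian), `residual_norm`, `fitted`,
#'   `converged`.
#' @export
fit_nanovisc <- function(curve, phi_occ, fix_a = NULL,
                         fit_r_min = !is.null(fix_a), weighted = TRUE,
                         n_starts = 8, interpolant = "quadrature") {
  if (!all(c("r_h_nm", "d_ratio") %in% names(curve)))
    stop("curve needs columns r_h_nm and d_ratio")
  if (nrow(curve) < 4) stop("need at least 4 points")
  if (any(curve$d_ratio <= 0)) stop("d_ratio values must be positive")
  r_h <- curve$r_h_nm; y <- curve$d_ratio
  sig <- if ("sigma" %in% names(curve)) curve$sigma else NA_real_
  w <- if (weighted && all(is.finite(sig)) && all(sig > 0)) 1 / sig^2
       else rep(1, length(y))
  model <- function(r_h, a, b, rc, rmin) {
    xi <- xi_hard_sphere(rc, phi_occ)
    reff <- r_eff_modified(r_h, rc, rmin, interpolant)
    exp(-b * (reff / xi)^a)
  }
  rc_grid <- exp(seq(log(max(min(r_h), 0.2)), log(10 * max(r_h)),
                     length.out = n_starts))
  b_grid <- exp(seq(log(0.2), log(20), length.out = n_starts))
  best <- NULL
  for (k in seq_len(n_starts)) {
    start <- list(b = b_grid[k], rc = rc_grid[k])
    lower <- c(b = 0, rc = 1e-3)
    upper <- c(b = Inf, rc = Inf)
    if (is.null(fix_a)) {
      start$a <- if (k %% 2 == 0) 1 else 0.6
      lower <- c(lower, a = 0.05); upper <- c(upper, a = 5)
    }
    if (fit_r_min) {
      start$rmin <- 0.2 * min(r_h[r_h > 0], 1)
      lower <- c(lower, rmin = 0); upper <- c(upper, rmin = Inf)
    }
    form <- if (is.null(fix_a) && fit_r_min)
      y ~ model(r_h, a, b, rc, rmin)
    else if (is.null(fix_a))
      y ~ model(r_h, a, b, rc, 0)
    else if (fit_r_min)
      y ~ model(r_h, fix_a, b, rc, rmin)
    else
      y ~ model(r_h, fix_a, b, rc, 0)
    fit <- tryCatch(
      minpack.lm::nlsLM(form, start = start, weights = w,
                        lower = lower[names(start)],
                        upper = upper[names(start)],
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (!is.null(fit)) {
      rn <- sum(w * residuals(fit)^2)
      if (is.null(best) || rn < best$rn) best <- list(fit = fit, rn = rn)
    }
  }
  if (is.null(best)) {
    # degenerate profiles (a flat curve makes the Jacobian singular at b = 0):
    # profile the one-parameter b fit over the grid of fixed shape parameters
    a_fix <- if (is.null(fix_a)) 1 else fix_a
    prof <- NULL
    for (rc in rc_grid) {
      g <- (r_eff_modified(r_h, rc, 0, interpolant) /
              xi_hard_sphere(rc, phi_occ))^a_fix
      sse <- function(b) sum(w * (y - exp(-b * g))^2)
      bb <- stats::optimize(sse, c(0, 100), tol = 1e-12)$minimum
      if (is.null(prof) || sse(bb) < prof$rn)
        prof <- list(rn = sse(bb), b = bb, rc = rc)
    }
    if (is.null(prof))
      stop("nanoviscosity fit failed to converge from all ", n_starts,
           " starts")
    params <- nanovisc_params(a = a_fix, b = prof$b, r_c_eff = prof$rc,
                              r_min = 0, phi_occ = phi_occ,
                              interpolant = interpolant)
    return(structure(list(params = params,
                          se = c(b = NA_real_, rc = NA_real_),
                          residual_norm = prof$rn,
                          fitted = d_ratio_nanovisc(r_h, params),
                          converged = TRUE, phi_occ = phi_occ),
                     class = "nanovisc_fit"))
  }
  cf <- coef(best$fit)
  se <- tryCatch(sqrt(diag(vcov(best$fit))), error = function(e)
    setNames(rep(NA_real_, length(cf)), names(cf)))
  params <- nanovisc_params(a = if (is.null(fix_a)) cf[["a"]] else fix_a,
                            b = cf[["b"]], r_c_eff = cf[["rc"]],
                            r_min = if (fit_r_min) cf[["rmin"]] else 0,
                            phi_occ = phi_occ, interpolant = interpolant)
  structure(list(params = params, se = se, residual_norm = best$rn,
                 fitted = d_ratio_nanovisc(r_h, params),
                 converged = TRUE, phi_occ = phi_occ),
            class = "nanovisc_fit")
}

#' @export
print.nanovisc_fit <- function(x, ...) {
  p <- x$params
  cat(sprintf(paste0("<nanovisc_fit> a = %.3f, b = %.3f, r_c_eff = %.3f nm, ",
                     "r_min = %.3f nm (resid norm %.3g)\n"),
              p$a, p$b, p$r_c_eff, p$r_min, x$residual_norm))
  invisible(x)
}
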