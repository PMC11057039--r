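# Mean-squared displacement analysis and the linear slowdown law
# D/D0 = 1 - kappa * phi_occ (intercept fixed at 1).

#' Time- and particle-averaged mean-squared displacement
#'
#' Averages squared displacements over all frame pairs at each lag (and over
#' all particles of the selected species), for lags up to
#' `max_lag_fraction` of the total (post-equilibration) time span.
#'
#' @param traj A `bd_trajectory` (from [run_trajectory()] or
#'   [generate_free_walk()]).
#' @param species Species label to analyze; `NULL` uses every particle.
#' @param max_lag_fraction Largest lag as a fraction of the span (default
#'   0.25; long lags average few effectively independent pairs, so the
#'   variance of the estimate grows roughly linearly with this fraction).
#' @param n_blocks Particle blocks retained for block-resampled uncertainties
#'   downstream (default 5).
#' @return An object of class `msd_curve`: `lag_times` (us, starting at 0),
#'   `msd` (nm^2), `n_pairs` per lag, `species`, and a per-block MSD matrix
#'   for uncertainty estimation.
#' @export
compute_msd <- function(traj, species = NULL, max_lag_fraction = 0.25,
                        n_blocks = 5) {
  stopifnot(inherits(traj, "bd_trajectory"))
  keep_frames <- which(traj$equilibrated)
  if (length(keep_frames) < 2) stop("need at least 2 usable frames")
  if (is.null(species)) {
    idx <- seq_along(traj$labels)
  } else {
    idx <- which(traj$labels == species)
    if (length(idx) == 0) stop("no particles with label '", species, "'")
  }
  arr <- traj$unwrapped[keep_frames, idx, , drop = FALSE]
  times <- traj$times[keep_frames]
  nf <- length(keep_frames)
  max_lag <- max(1L, floor(max_lag_fraction * (nf - 1)))
  lags <- seq_len(max_lag)
  res <- cpp_msd(arr, as.integer(lags))
  dt_frame <- times[2] - times[1]
  n_blocks <- min(n_blocks, length(idx))
  block_id <- ((seq_along(idx) - 1L) %% n_blocks) + 1L
  block_msd <- vapply(seq_len(n_blocks), function(b)
    rowMeans(res$per_particle[, block_id == b, drop = FALSE]),
    numeric(length(lags)))
  structure(list(lag_times = c(0, lags * dt_frame),
                 msd = c(0, res$msd),
                 n_pairs = c(length(idx) * nf, res$n_pairs),
                 species = if (is.null(species)) "all" else species,
                 block_msd = block_msd),
            class = "msd_curve")
}

#' Long-time diffusion coefficient from an MSD curve
#'
#' Weighted least-squares fit of `msd = 6*D*tau` over the last half-decade of
#' available lags (`tau >= tau_max/sqrt(10)`), with pair counts as weights.
#' The local logarithmic slope of the MSD in the window must be close to 1;
#' values below `min_exponent` trigger a "not converged to the diffusive
#' regime" warning. The standard error comes from block resampling over
#' particles when block curves are available, else from the fit residuals.
#'
#' @param msd An `msd_curve`.
#' @param min_exponent Subdiffusion guard on d log(msd)/d log(tau) (default 0.9).
#' @return List with `d` (nm^2/us), `se`, `window` (lag range used), and
#'   `local_exponent`.
#' @export
long_time_d <- function(msd, min_exponent = 0.9) {
  stopifnot(inherits(msd, "msd_curve"))
  tau <- msd$lag_times
  pos <- which(tau > 0)
  win <- pos[tau[pos] >= max(tau) / sqrt(10)]
  if (length(win) < 5) stop("fewer than 5 lags in the long-time window")
  t_w <- tau[win]; m_w <- msd$msd[win]; w <- msd$n_pairs[win]
  d_hat <- sum(w * t_w * m_w) / (6 * sum(w * t_w^2))
  if (all(m_w > 0)) {
    expo <- coef(lm(log(m_w) ~ log(t_w)))[2]
    if (expo < min_exponent)
      warning(sprintf(paste0("MSD local exponent %.2f < %.2f in the fit ",
                             "window: not converged to the diffusive regime"),
                      expo, min_exponent))
  } else expo <- NA_real_
  if (!is.null(msd$block_msd) && ncol(msd$block_msd) >= 2) {
    d_blocks <- vapply(seq_len(ncol(msd$block_msd)), function(b) {
      mb <- msd$block_msd[win - 1, b]  # block matrix has no lag-0 row
      sum(w * t_w * mb) / (6 * sum(w * t_w^2))
    }, numeric(1))
    se <- sd(d_blocks) / sqrt(length(d_blocks))
  } else {
    resid <- m_w - 6 * d_hat * t_w
    s2 <- sum(w * resid^2) / max(1, length(win) - 1)
    se <- sqrt(s2 / (36 * sum(w * t_w^2)))
  }
  list(d = d_hat, se = se, window = range(t_w),
       local_exponent = unname(expo))
}

#' Build a slowdown curve table
#'
#' @param abscissa Numeric vector (phi_occ decimals or R_H in nm).
#' @param d_ratio D/D0 values.
#' @param sigma Standard errors (optional).
#' @param abscissa_name Column name, `"phi_occ"` (default) or `"r_h_nm"`.
#' @return Data frame of class `slowdown_curve`.
#' @export
slowdown_curve <- function(abscissa, d_ratio, sigma = NULL,
                           abscissa_name = c("phi_occ", "r_h_nm")) {
  abscissa_name <- match.arg(abscissa_name)
  if (any(d_ratio <= 0) || any(d_ratio > 1.05))
    stop("d_ratio values must lie in (0, 1.05]")
  if (!is.null(sigma) && any(sigma < 0)) stop("sigma must be >= 0")
  df <- data.frame(abscissa, d_ratio = d_ratio,
                   sigma = if (is.null(sigma)) NA_real_ else sigma)
  names(df)[1] <- abscissa_name
  class(df) <- c("slowdown_curve", "data.frame")
  df
}

#' Fit the linear slowdown law D/D0 = 1 - kappa*phi_occ
#'
#' Least squares with the intercept fixed at exactly 1: the phi = 0 anchor
#' (D/D0 = 1) is required to be present and is enforced, not fitted. Points
#' are weighted by `1/sigma^2` when finite sigmas are provided (the fit is
#' invariant to a uniform rescaling of all sigmas).
#'
#' @param curve A [slowdown_curve()] (or data frame) over `phi_occ` with
#'   `d_ratio` and optional `sigma`.
#' @param weighted Use `1/sigma^2` weights when sigmas are available
#'   (default `TRUE`); `FALSE` forces the unweighted fit.
#' @return List of class `kappa_fit`: `kappa`, `kappa_se`, `r_squared`,
#'   `n_points`, `residuals`.
#' @export
fit_kappa <- function(curve, weighted = TRUE) {
  if (!all(c("phi_occ", "d_ratio") %in% names(curve)))
    stop("curve needs columns phi_occ and d_ratio")
  phi <- curve$phi_occ; y <- curve$d_ratio
  if (length(unique(phi)) < 3)
    stop("need at least 3 distinct phi_occ values")
  if (max(phi) <= min(phi)) stop("all-identical abscissa")
  if (!any(phi == 0))
    stop("the phi_occ = 0 anchor (D/D0 = 1) must be present")
  fit_idx <- which(phi > 0)
  sig <- if ("sigma" %in% names(curve)) curve$sigma[fit_idx] else NA_real_
  w <- if (weighted && all(is.finite(sig)) && all(sig > 0)) 1 / sig^2
       else rep(1, length(fit_idx))
  x <- phi[fit_idx]; z <- 1 - y[fit_idx]      # z = kappa * phi
  kappa <- sum(w * x * z) / sum(w * x^2)
  resid <- z - kappa * x
  n <- length(fit_idx)
  s2 <- sum(w * resid^2) / max(1, n - 1)
  kappa_se <- sqrt(s2 / sum(w * x^2))
  pred <- 1 - kappa * phi
  r_squared <- 1 - sum((y - pred)^2) / sum((y - mean(y))^2)
  structure(list(kappa = kappa, kappa_se = kappa_se, r_squared = r_squared,
                 n_points = n, residuals = y[fit_idx] - pred[fit_idx]),
            class = "kappa_fit")
}

#' @export
print.kappa_fit <- function(x, ...) {
  cat(sprintf("<kappa_fit> kappa = %.4f +/- %.4f (R^2 = %.4f, n = %d)\n",
              x$kappa, x$kappa_se, x$r_squared, x$n_points))
  invisible(x)
}
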