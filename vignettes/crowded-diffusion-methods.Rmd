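---
title: "Methods: hard-sphere Brownian dynamics and size-dependent diffusion in crowded media"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: hard-sphere Brownian dynamics and size-dependent diffusion in crowded media}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crowdiff)
```

## The scientific question

How strongly does macromolecular crowding slow the diffusion of a tracer,
and how does that slowdown depend on the tracer's size? In dilute solution
the Stokes–Sutherland–Einstein (SSE) relation

$$D_0 = \frac{k_B T}{6 \pi \eta_0 R_H}$$

ties the diffusion coefficient to the hydrodynamic radius $R_H$ and the
solvent viscosity $\eta_0$. In a crowded medium — a concentrated Ficoll
solution, or the bacterial cytoplasm at ~40% occupied volume — the measured
$D$ falls below $D_0$, and the package quantifies that fall with the linear
slowdown law

$$D/D_0 = 1 - \kappa\,\phi_{occ},$$

where $\phi_{occ}$ is the occupied volume fraction (a decimal throughout
the package; percentages appear only in I/O) and $\kappa$ is a single
dimensionless slowdown parameter. `crowdiff` provides four independent
routes to $D/D_0$ and $\kappa$: hard-sphere Brownian dynamics (BD),
excluded-volume Monte Carlo combined with the Maxwell–Garnett effective
medium result, a closed-form linear theory, and a length-scale-dependent
nanoviscosity model. Synthetic pulsed-gradient stimulated-echo (PGSTE) NMR
data generation and fitting stand in for spectrometer measurements.

## Units

Internal units are nm, µs, K, and mPa·s; diffusivities are nm²/µs
(1 nm²/µs = 10⁻¹² m²/s). This keeps Brownian step lengths of order
10⁻³–10⁻¹ nm and all exponents well away from under/overflow. PGSTE
quantities follow NMR convention (T/m, ms, m²/s) because the
Stejskal–Tanner $b$-factor is conventionally quoted in s/m². CODATA values
of $k_B$ and $N_A$ are hard-coded at full published precision. The default
solvent viscosity, 0.89 mPa·s (water at 298 K), is a configuration choice —
crowded-sample viscosities are precisely what the models predict, not an
input.

## Brownian dynamics of hard spheres

Particles are hard spheres in a cubic periodic box (minimum-image
convention everywhere). The propagator is overdamped forward Euler without
hydrodynamic interactions: each particle is displaced by an independent
Gaussian vector of per-axis variance $2 D_0(\text{species})\,dt$, with
$D_0$ from the SSE relation. Inertia, rotations, torques and interparticle
attractions are all absent by construction.

Hard cores are enforced by an elastic displacement correction in the
Heyes–Melrose style: after every Euler step, each overlapping pair is moved
apart along its center line exactly back to contact, and sweeps repeat
until no overlap remains. The correction is shared between the two
particles in proportion to their dilute mobilities ($D_0$), which reduces
to the symmetric split for equal spheres and lets small particles yield to
large ones; this choice preserves diffusive scaling at small $dt$ and is
standard for BD of hard spheres. Non-convergence within 100 sweeps aborts
the run — it signals a timestep or density outside the scheme's validity.

**Timestep.** The package refuses any $dt$ for which the RMS free step
$\sqrt{2 D_0^{max} dt}$ exceeds 10% of the smallest radius in the system,
and defaults to 5%. At 5% the residual discretization bias of the
correction scheme is at the percent level, which is below the statistical
resolution of the runs shipped here.

**Initial configurations.** Random sequential addition (RSA), largest
species first, places particles without overlap. Largest-first ordering
matters: small species slot into the interstices that remain, which is how
the polydisperse cytoplasm composition packs directly at $\phi_{occ} =
0.426$. Monodisperse RSA, by contrast, jams near $\phi \approx 0.38$, so
on insertion failure (or for targets above 0.45) the builder switches to a
compression protocol — insert in a box inflated to $\phi = 0.25$, then
shrink the edge in 0.5% stages with overlap-relaxation sweeps after each.
The compression machinery is packing plumbing, not physics: configurations
are subsequently equilibrated by the BD run itself, and the analysis
discards an equilibration segment (10% of steps by default).

## From trajectories to D and kappa

The mean-squared displacement (MSD) is averaged over all frame pairs at
each lag and over all particles of the analyzed species, from unwrapped
coordinates (periodic wrapping is never allowed to truncate a
displacement). The long-time diffusion coefficient is a weighted
least-squares fit of $\mathrm{MSD} = 6 D \tau$ over the last half-decade of
available lags, with pair counts as weights.

Two guards make the estimate honest:

* **Subdiffusion guard.** The local exponent
  $d\log \mathrm{MSD}/d\log\tau$ in the fit window must exceed 0.9;
  otherwise the fit warns that the run has not reached the diffusive
  regime. Short crowded runs fail this check loudly rather than silently
  returning a too-large $D$.
* **Block uncertainties.** Particles are split into five blocks
  (independent at the 0.2 mM tracer concentrations used), and the SE of
  $D$ is the dispersion of per-block estimates.

The default analysis window caps lags at 10% of the trajectory span
(`max_lag_fraction` in `compute_msd()`, default 0.25; the pipeline drivers
use 0.1). The variance of a time-averaged MSD grows roughly linearly in
$\tau/T$, so short-lag windows are strongly preferred statistically; the
subdiffusion guard protects the other flank.

`fit_kappa()` fits $D/D_0 = 1 - \kappa \phi_{occ}$ with the intercept
pinned at exactly 1 — the functional form demands it, and the $\phi = 0$
control run instead serves as an independent calibration that the pipeline
recovers the SSE $D_0$. Points are weighted by $1/\sigma^2$ when
uncertainties are present; the estimate and its residual-based SE are
invariant to a uniform rescaling of all $\sigma$.

**Run lengths and replicates.** A tracer only shows its long-time $D$
after diffusing well past the crowder scale. The shipped runs use ~150
particles and step counts chosen so the fitted lag window corresponds to
displacements of 2–3 crowder diameters; required steps scale as
$(0.8/R_H)^2$ (the stable $dt$ grows as $R_H^3$ while the needed physical
time grows only as $R_H$). The metabolite-sized sweep (0.8 nm: 100
tracers, 50 crowders, 2 × 4×10⁵ steps) additionally averages two
independently built configurations per state point
(`simulate_state_point(n_replicates=)`), the standard way to beat down
configuration-level fluctuations at fixed run length; the larger tracers
(2.5 nm: 1.5×10⁵ steps; 5.1 nm self-crowding: 5×10⁴ steps, tracking the
crowders themselves) resolve their stronger slowdowns in single runs.
These workstation-scale choices give per-point uncertainties near 1%,
resolving $\kappa$ to a few percent; longer runs simply tighten the same
estimates.

## Excluded volume and the Maxwell–Garnett route

A tracer of radius $R_H$ is excluded not from the crowders' occupied
volume but from the larger region within $R_c + R_H$ of any crowder
center. `phi_ex_mc()` estimates this excluded fraction $\phi_{ex}$ by
Widom-style insertion: uniform random placements, counting the overlap
fraction, averaged over several configurations (BD-sampled by default,
static packings as a faster option), with the SE taken over configurations.
Two closed forms bracket it: the cubic estimate
$\phi_{occ}(1 + R_H/R_c)^3$, which neglects exclusion-shell overlaps and
overestimates once shells interpenetrate, and its linearization
$\phi_{occ}(1 + 3R_H/R_c)$.

The Maxwell–Garnett effective-medium result for a point tracer among
impermeable inclusions is used in its linear form $D/D_0 = 1 -
\phi_{ex}/2$ (κ = ½ for a point tracer; at $\phi_{ex} = 0.10$ both the
linear and the full rational form give 0.95 to the printed precision).
Chaining it with the linear excluded-volume form yields the closed
size-dependent theory

$$\kappa(R_H) = \tfrac12\left(1 + 3 R_H/R_c\right),$$

which predicts κ = 2 for self-crowding ($R_H = R_c$). The identity
`mg_diffusivity(phi_ex_linear(phi, R, Rc))` $\equiv 1 -$
`kappa_linear_theory(R, Rc)` $\cdot \phi$ holds algebraically and is
asserted to machine precision in the tests. BD with *mobile* crowders sits
above the static-crowder Maxwell–Garnett/MC prediction at larger $R_H$ —
crowder motion lets tracers through — so agreement of the linear theory
with BD at all sizes should be read as partly coincidental.

## Nanoviscosity model

For polydisperse, cytoplasm-like crowding the slowdown is nonlinear in
tracer size, and the package fits the phenomenological nanoviscosity law

$$\frac{D}{D_0} = \frac{\eta_0}{\eta(R_H)} = \exp\left[-b\,(R_{eff}/\xi)^a\right],$$

with $\xi = R_g\,\psi_{rcp}(1-\phi_{occ})/\phi_{occ}$ the intercrowder gap
($\psi_{rcp} = \phi/(1-\phi)$ at random close packing $\phi = 0.638$,
≈ 1.76; $R_g = R_c$ for hard spheres) and $R_{eff}$ an effective radius
interpolating between the tracer radius (small tracers) and the crowder
radius (large tracers).

Design choices that were genuinely open:

* **The interpolant.** The package adopts the quadrature form $R_{eff} =
  R_H R_c/\sqrt{R_H^2 + R_c^2}$, which satisfies both limits; a harmonic
  alternative is selectable (`interpolant = "harmonic"`). The limits, not
  the specific interpolant, are treated as the contract — any difference is
  absorbed into the fitted $b$.
* **The minimal length.** With the plain model, $D \to D_0$ as $R_H \to
  0$ regardless of crowding, which contradicts both measurements and the
  excluded-volume route. The extension evaluates $R_{eff}$ at $R_H +
  R_{min}$; with exponent $a = 1$ this restores the linear slowdown law at
  small sizes with $\kappa$ affine in $R_H$ (verified by numerical
  differentiation in the tests). $R_{min} = 0$ disables it exactly.
* **Step-like exponent.** Where a size-dependent exponent is wanted,
  `nanovisc_params(a_small=)` switches logistically (in $\log R_H$,
  configurable width) between a small-tracer and a large-tracer plateau;
  only the two plateaus are physically motivated, the switch shape is a
  smoothness choice.
* **Fit mode for cytoplasm-like curves.** `run_cytoplasm(fit = TRUE)`
  fits with `a` fixed at 1 and the minimal length free. Two reasons: the
  curves include metabolite-sized points, where the plain model's forced
  $D \to D_0$ cannot hold; and with data ending at ribosome size the free
  exponent rides a $b$–$R_c^{eff}$ degeneracy ridge toward arbitrarily
  large crowder radii, whereas the fixed-exponent mode lands on
  interpretable parameters. Both modes remain available in
  `fit_nanovisc()`.
* **Multi-start fitting.** The model is prone to local minima (strongly
  correlated $b$ and $R_c^{eff}$), so `fit_nanovisc()` launches 8 starts
  log-spaced in $b$ and $R_c^{eff}$ and keeps the best weighted residual.
  Degenerate inputs (a flat curve) make the Jacobian singular at the $b =
  0$ boundary; the fitter then falls back to profiling the one-parameter
  $b$ fit over the shape grid, so $\hat b \to 0$ rather than an error.

## Synthetic PGSTE-NMR data

The generator emulates what a diffusion-NMR measurement delivers after
peak integration: a normalized attenuation table $I/I_0$ versus gradient
strength $g$, following the Stejskal–Tanner form

$$I/I_0 = \exp\left[-D\,\gamma^2 g^2 \delta^2 (\Delta - \delta/3)\right]$$

with additive Gaussian noise on the normalized intensities — adequate for
the high signal-to-noise regime of concentrated small-molecule samples.
Defaults (¹H γ, δ = 2 ms, Δ = 100 ms, 16 gradients to 0.5 T/m) are
plausible modern-spectrometer values and fully configurable. What the
generator does **not** emulate: spectral lineshapes, peak overlap and
integration, Rician noise at low SNR, convection artifacts, or solvent
corrections — so recovery tests validate the fitting chain, not
spectrometer practice. Every generator records its truth and seed, and
every fitter consuming generator output is tested for calibrated recovery
(bias within 2 SE over hundreds of replicates, CI coverage between 90 and
99% at nominal 95%).

`fit_attenuation()` fits $I = I_0 e^{-b(g) D}$ by nonlinear least squares
in $(I_0, D)$, initialized from the log-linear fit and with $D$ scaled to
10⁻¹⁰ m²/s internally for conditioning.

## The synthetic cytoplasm composition

The packaged composition
(`inst/extdata/cytoplasm_composition_synthetic.csv`) is a **constructed
stand-in**, not a measured proteome: nine hard-sphere species from 1.7 to
13 nm, including a GFP-like 2.4 nm species and a ribosome-like 13 nm
species carrying roughly a third of the macromolecular volume, with counts
chosen so the default build (~370 macromolecules plus 50 metabolites of
0.8 nm) packs to $\phi_{occ} = 0.426$ in a ~55 nm box. It reproduces the
qualitative structure of coarse-grained *E. coli* cytoplasm models — broad
size polydispersity with ribosomes dominating the large end — and users
with a specific proteome should supply their own table
(`label,radius_nm,count` CSV).

## What passing tests do and do not show

The synthetic generators and BD runs validate internal consistency: the
propagator reproduces free diffusion; crowded runs reproduce the linear
slowdown law and the growth of κ with size; the fitters recover the truths
of their own generating models with calibrated uncertainties. None of this
certifies behavior of real crowders: Ficoll porosity and polydispersity,
hydrodynamic interactions (deliberately absent), chemical interactions,
and non-spherical shapes all lie outside the model class, and where they
matter real data will deviate from these predictions in ways the test
suite cannot detect.

## Known limitations

* No hydrodynamic interactions: κ values for larger tracers are
  systematically lower than HI-resolving methods would give.
* Finite-time bias: the long-time $D$ is approached from above, so
  under-converged runs underestimate κ. The subdiffusion guard flags, but
  cannot remove, this bias; the shipped run lengths keep it within the
  quoted uncertainties.
* Finite-size effects: periodic boxes of ~10 crowder diameters suppress
  long-range correlations; no box-size extrapolation is attempted.
* RSA/compression initial states are disordered but not strictly
  equilibrium hard-sphere fluids; the discarded equilibration segment
  relaxes the structure factor at the scales probed.
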