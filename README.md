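# crowdiff

Size-dependent tracer diffusion in macromolecularly crowded media:
hard-sphere Brownian dynamics, excluded-volume Monte Carlo,
Maxwell–Garnett and nanoviscosity predictors, and synthetic PGSTE-NMR
data with Stejskal–Tanner fitting.

## The problem

Metabolite-sized molecules (sub-nanometer to a few nanometers) diffuse
through cell interiors where macromolecules occupy up to ~40% of the
volume. How much crowding slows a tracer — and how that slowdown depends
on the tracer's hydrodynamic radius `R_H` — controls the rates of
diffusion-limited biochemistry, and reported answers disagree. This
package provides a tested computational pipeline for the question, aimed
at biophysicists and simulators who want reproducible slowdown curves and
parameter fits rather than one-off scripts.

The central observable is the relative diffusivity `D/D0`, with `D0` the
dilute-limit Stokes–Sutherland–Einstein (SSE) value
`D0 = kB*T / (6*pi*eta0*R_H)`. Under monodisperse crowding at occupied
volume fraction `phi_occ`, `D/D0` falls linearly,

    D/D0 = 1 - kappa * phi_occ

and the slowdown parameter `kappa` summarizes the effect of crowding on a
given tracer size. The package computes `kappa(R_H)` four independent
ways:

1. **Brownian dynamics** of hard-sphere crowder/tracer mixtures (forward
   Euler, Heyes–Melrose hard-core correction, no hydrodynamic
   interactions), with long-time `D` extracted from time- and
   particle-averaged MSDs;
2. **Excluded-volume Monte Carlo**: Widom-style insertion gives the
   volume fraction `phi_ex` excluded to a finite tracer, which feeds the
   Maxwell–Garnett point-tracer result `D/D0 = 1 - phi_ex/2`;
3. **Closed-form linear theory** `kappa(R_H) = 0.5*(1 + 3*R_H/R_c)`
   (κ = ½ for a point tracer, κ = 2 for self-crowding);
4. **Nanoviscosity model** `D/D0 = exp[-b*(R_eff/xi)^a]` for polydisperse,
   cytoplasm-like crowding, with multi-start nonlinear fitting.

A synthetic-data module generates Stejskal–Tanner PGSTE-NMR attenuation
series, free-diffusion random walks, and noisy slowdown curves with
recorded ground truth, so every fitter in the package is tested for
calibrated recovery.

## Worked example

Slowdown of a metabolite-sized tracer (`R_H` = 0.8 nm) among Ficoll70-like
crowders (`R_c` = 5.1 nm), at a workstation-friendly scale:

```r
library(crowdiff)

# analytic anchors
sse_diffusivity(0.8)            # 306.5621 nm^2/us: dilute D0 at 298 K, 0.89 mPa.s
kappa_linear_theory(0.8, 5.1)   # 0.7353: linear excluded-volume prediction
mg_diffusivity(0.10)            # 0.95: point tracer at 10% occupancy

# BD phi sweep: build -> simulate -> MSD -> kappa (~1 min)
sweep <- run_phi_sweep(r_h = 0.8, phi_grid = c(0, 0.1, 0.2),
                       n_crowders = 60, n_tracers = 50,
                       n_steps = 1e5, seed = 1)
sweep$curve
#>   phi_occ   d_ratio      sigma
#> 1     0.0 1.0000000 0.01853994
#> 2     0.1 0.9511179 0.02264187
#> 3     0.2 0.9057690 0.01976601
sweep$kappa_fit
#> <kappa_fit> kappa = 0.4740 +/- 0.0065 (R^2 = 0.9994, n = 2)
```

The `d_ratio` column is the tracers' long-time `D` relative to the SSE
`D0`; `sigma` is a block SE over particles. Crowding at 20% occupancy
costs this tracer ~9% of its mobility. The fitted `kappa` sits below the
static-crowder theory value (0.74): partly real physics — mobile crowders
let small tracers through — and partly finite-run bias, since short runs
approach the long-time `D` from above. `analysis/03_size_sweep.R` uses
converged run lengths and reports the residual gap honestly alongside the
theory column.

The numbered scripts under `analysis/` reproduce the full study line:
free-diffusion calibration, the phi sweep, `kappa(R_H)` ordering, the
excluded-volume method comparison, the polydisperse cytoplasm run, and
the PGSTE recovery study. Each writes its tables under `results/`.

## Layout

- `R/`, `src/` — package code (R interface, Rcpp simulation core)
- `analysis/` — numbered study drivers (thin scripts over the package)
- `tests/testthat/` — unit, property and end-to-end acceptance tests
- `vignettes/crowded-diffusion-methods.Rmd` — model assumptions,
  numerical choices, limitations
- `inst/extdata/cytoplasm_composition_synthetic.csv` — packaged
  synthetic cytoplasm composition (constructed stand-in; bring your own
  table for a specific proteome)
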