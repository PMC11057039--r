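Package: crowdiff
Title: Size-Dependent Tracer Diffusion in Macromolecularly Crowded Media
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Brownian dynamics of hard-sphere crowder/tracer mixtures without
    hydrodynamic interactions, long-time self-diffusion coefficients from
    mean-squared displacements, the linear slowdown law D/D0 = 1 - kappa*phi
    and its excluded-volume and Maxwell-Garnett predictors, length-scale
    dependent nanoviscosity models for polydisperse (cytoplasm-like) crowding,
    and synthetic pulsed-gradient stimulated-echo (PGSTE) NMR attenuation data
    with Stejskal-Tanner fitting. Includes non-overlapping system builders for
    monodisperse Ficoll-like mixtures and a coarse-grained cytoplasm model,
    Widom-style excluded-volume Monte Carlo insertion, and config-driven
    experiment orchestration with seeded, reproducible outputs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    minpack.lm,
    jsonlite,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
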