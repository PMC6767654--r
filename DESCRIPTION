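Package: glymphuq
Title: Uncertainty Quantification of Tracer Transport in Brain Parenchyma
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Monte Carlo uncertainty quantification for intrathecal tracer
    transport into the brain parenchyma. Solves a convection-diffusion-reaction
    equation with stochastic coefficients (gamma-distributed diffusivity,
    Matern-field diffusivity, divergence-free glymphatic velocity fields and a
    radial inflow field with drainage) on labeled tetrahedral meshes using
    piecewise-linear finite elements with mass lumping and implicit midpoint
    time stepping. Includes a synthetic two-compartment brain-like mesh
    generator, a mass-conserving subarachnoid-space boundary model, regional
    quantities of interest with censored activation times, and Monte Carlo
    summaries with empirical prediction intervals.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    stats,
    utils,
    xml2
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
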