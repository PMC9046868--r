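Package: melanosim
Title: Phenotype-Structured Simulation of Melanoma Heterogeneity Under
    Targeted Therapy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Deterministic simulator of non-genetic melanoma heterogeneity
    under targeted therapy. The tumor is a structured population: a single
    cell density over two spatial and two cell-state ("gene-expression map")
    dimensions evolves by a continuity equation with spatial diffusion,
    chemotaxis and haptotaxis, cell-state advection and anisotropic
    cell-state diffusion, nutrient-limited proliferation and state-dependent
    drug kill, coupled to five two-dimensional environment fields
    (extracellular nutritional environment, nutrient, acid, and two drug
    concentrations). Includes continuous, sequential-combination and
    adaptive (threshold/hysteresis) treatment schedulers, heterogeneity and
    spatial-zoning metrics, a Monte Carlo particle oracle for solver
    verification, a YAML configuration layer with scenario presets, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    methods,
    Rcpp (>= 1.0.0),
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
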