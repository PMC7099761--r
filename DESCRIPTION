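Package: frugalNPZD
Title: Variable-Stoichiometry NPZD Water-Column Model with Phosphate-Frugal
    Uptake
Version: 0.2.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: A desk-scale nutrient-phytoplankton-zooplankton-detritus (NPZD)
    ecosystem model with three plankton functional types whose internal P:N
    uptake ratio either follows the fixed Redfield value (1:16) or varies
    linearly with ambient phosphate after the empirical "line of frugality".
    Provides squared Michaelis-Menten nitrogen and phosphorus limitation
    factors with a Liebig minimum rule, a mass-conservative phosphorus ledger
    for every organic pool, a compiled 0-D box and 1-D column integrator with
    implicit vertical diffusion and upwind sinking, synthetic seasonal forcing
    presets emulating a co-limited northwestern and a strongly
    phosphate-depleted eastern Mediterranean regime, twin-simulation
    experiments, and diagnostics for nutrient ratios, limitation climatology,
    deep chlorophyll maxima and Taylor-diagram model skill.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    S4Vectors,
    SummarizedExperiment,
    jsonlite,
    rlang
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
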