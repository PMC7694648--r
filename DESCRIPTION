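Package: isoflux
Title: Metabolic Flux Analysis from Stable Isotope Labeling Patterns
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Steady-state and isotopically non-stationary 13C metabolic flux
    analysis (MFA). Parses atom-transition reaction networks, decomposes them
    into elementary metabolite unit (EMU) networks, predicts mass isotopomer
    distributions (MIDs) from fluxes and tracer compositions by solving the
    labeling-balance equations, and estimates free fluxes (and metabolite pool
    sizes in the non-stationary case) from measured MIDs by multi-start
    variance-weighted least squares. Uncertainty is quantified with
    profile-likelihood confidence intervals, two-dimensional confidence-region
    rasters for tracer evaluation, and Monte-Carlo sampling. A brute-force
    isotopomer simulator is included as an independent cross-check of the EMU
    solver.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    deSolve,
    graphics,
    minpack.lm,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
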