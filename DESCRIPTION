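Package: smlssi
Title: Precision Bounds and Simulation for Single-Molecule Localization
    by Sequential Structured Illumination
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Forward model, Cramer-Rao precision bounds, and
    maximum-likelihood localization for single-molecule localization
    schemes that interrogate an emitter with a sequence of doughnut-beam
    intensity minima (MINFLUX and raster-scanned minima, RASTMIN),
    including multiphoton excitation of arbitrary order. Computes
    position-dependent Fisher information and sigma_CRB precision maps
    over the field of view, samples multinomial photon-count records with
    uniform background at a given signal-to-background ratio, localizes
    by maximum likelihood, and validates estimator efficiency against the
    bound by Monte Carlo simulation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    yaml,
    jsonlite,
    tiff
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
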