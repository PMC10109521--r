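Package: gpla
Title: Generalized Phase Locking Analysis of Multichannel Spike-Field Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Dimensionality reduction of multivariate spike-field coupling.
    Builds a complex coupling matrix between spike trains and band-limited
    analytic local field potentials (LFP), extracts a generalized phase
    locking value (gPLV) together with spike and LFP singular vectors, and
    assesses significance either with spike-jitter surrogates or with a fast
    analytical test based on the Marchenko-Pastur law for the singular
    spectrum of whitened coupling matrices. Includes synthetic benchmark
    generators (phase-locked Poisson spike trains, oscillation-mixture LFPs,
    two-population neural field simulations) and linearized neural mass and
    neural field models used to interpret the extracted coupling patterns.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    Matrix,
    data.table,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
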