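Package: glasscoh
Title: Simulation and Analysis of Polar Glass-Pattern fMRI Block Designs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying the blood-oxygen-level-dependent (BOLD)
    response of human visual cortex to polar Glass patterns of varying
    coherence. Generates the stimuli (dipole fields with circular or
    starburst polar orientation rules, rendered under an annular
    raised-cosine aperture), builds first-order counterbalanced block
    designs, simulates multi-participant node-level BOLD cohorts with
    canonical hemodynamic responses, Legendre drift, motion nuisance and
    ARMA(1,1) noise, and runs the analysis chain: prewhitened general
    linear model, percent-signal-change conversion, FDR node selection,
    orthogonal-polynomial trend contrasts with per-participant permutation
    tests, and the behavioral lagged-correlation analysis with a
    repeated-measures ANOVA.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    png,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
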