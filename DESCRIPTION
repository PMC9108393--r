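Package: infilsim
Title: Chemotaxis Modelling and Surrogate-Based Calibration of Immune
    Cell Infiltration in a Gut-on-a-Chip
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Mechanistic modelling of peripheral blood mononuclear cell
    (PBMC) infiltration into a three-channel microfluidic gut
    epithelium model. Provides a one-dimensional
    reaction-diffusion-chemotaxis system with a receptor-law
    chemotactic sensitivity and piecewise-constant motilities across
    the matrix/epithelium interface, solved with a conservative finite
    volume scheme; quantification of segmented imaging particle tables
    into declumped, spatially binned cell counts; a Kriging
    (Gaussian-process) surrogate optimiser with expected-improvement
    acquisition, differential-evolution inner search, batch sampling
    criteria and domain reduction for fitting the model to binned
    spatiotemporal counts; practical-identifiability contour scans,
    residual heatmaps and condition-difference surfaces; and a
    synthetic-data generator emulating the study design for end-to-end
    testing without access to raw imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    jsonlite,
    lhs,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
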