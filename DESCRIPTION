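Package: pairdiff
Title: Pairmate Pattern Differentiation Analysis for Event-Related fMRI
Version: 0.1.0
Authors@R: person("pairdiff", "maintainers", email = "pairdiff@example.org",
    role = c("aut", "cre"))
Description: Simulation and analysis pipeline for studying learning-driven
    differentiation of similar memory representations with multi-voxel
    pattern analysis. Generates seeded experimental designs for a pairmate
    scene-learning paradigm, simulates ground-truth voxel patterns with
    condition-dependent pairmate coupling and BOLD time series with AR(1)
    noise, estimates per-stimulus activity patterns (t-maps) with a
    double-gamma HRF GLM and prewhitening, computes cross-set Fisher-z
    similarity matrices and scene pair difference scores, and links
    representational overlap to memory interference with mixed-effects
    logistic regression and likelihood-ratio tests.
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
    tools,
    lme4,
    jsonlite,
    yaml
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
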