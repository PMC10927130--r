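Package: rptfusion
Title: Structure-Behavior Interaction Analysis for Operant Keypress Phenotyping
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for discriminating clinical groups through statistical
    interactions between operant keypress reward/aversion behavior and
    normalized brain-structure volumes. Implements relative preference
    theory (RPT) feature extraction from per-picture keypress counts
    (value, limit and trade-off functions; Shannon-entropy based metrics),
    a per-group structure-behavior regression grid with demographic
    covariate screening, Cook's-distance outlier filtering, standardized
    coefficients and Benjamini-Hochberg q-values, a beta-matrix heatmap
    comparison framework (valence, intensity and sign-direction tests),
    Kruskal-Wallis/Dunn feature selection, and leave-one-out k-nearest
    neighbor classification with a Mahalanobis transform and class priors.
    Includes a synthetic cohort generator that plants known
    structure-behavior couplings for calibration and recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    tibble,
    ggplot2,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    readxl,
    optparse
Config/testthat/edition: 3
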