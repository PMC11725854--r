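Package: popcongruence
Title: Population Coding and Congruency Analysis of Actual and Observed Touch
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Analysis pipeline for trial-aligned spike-count data recorded
    under a factorial touch paradigm (actual vs. observed touch, to cheek or
    shoulder, with up to four touch types). Provides per-neuron linear tuning
    with FDR-corrected significance, a discriminability index against the
    pre-stimulus baseline, split-half cross-validated population-vector
    correlations, time-resolved diagonal linear discriminant decoding,
    exhaustive enumeration and BIC/cross-validated selection among congruency
    models that share selectivity patterns across sensory fields, and
    demixed-subspace / discrimination-axis generalization analyses across
    task contexts. A synthetic Poisson spike generator with known per-neuron
    congruency models and population-level compositional structure supplies
    ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    BiocGenerics,
    S4Vectors,
    rhdf5,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    ggplot2,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
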