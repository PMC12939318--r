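Package: signalflow
Title: Logical Steady-State and Dependency Analysis of Signed Signalling Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for qualitative analysis of signed, directed
    protein-signalling networks. Computes three-valued (Kleene) logical
    steady states under clamped input scenarios, model-predicted
    expression changes between scenarios, and the six-class dependency
    matrix that classifies every ordered node pair as a strong or weak
    activator or inhibitor, an ambivalent factor, or no effect, based on
    elementary signed paths and negative feedback loops. Supports in
    silico knockouts with dependency-change tracking, scoring of model
    predictions against cell-line and patient expression data (fold
    changes, q-value cut-offs, binomial point probabilities, cohort
    stratification), and seed-deterministic synthetic data generators so
    the whole pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    igraph,
    jsonlite,
    stats,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
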