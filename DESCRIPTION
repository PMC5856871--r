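Package: metaproc
Title: Post-Processing of Untargeted LC-MS and GC-MS Metabolomics Feature Matrices
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Turns a deconvoluted chromatography-mass spectrometry feature
    table into an analysis-ready matrix. Implements pooled-QC and blank-based
    feature filtering (missingness and relative standard deviation rules),
    missing-value imputation (small-value replacement, feature-wise k-nearest
    neighbours, iterative random-forest), probabilistic quotient and sum
    normalization, QC-anchored robust LOESS signal-drift and batch correction,
    and accurate-mass metabolite annotation against compound tables via an
    adduct model. Includes a synthetic-data generator with cell-level ground
    truth for validating every stage, a config-driven pipeline runner with
    machine-readable stage reports, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    randomForest
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
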