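Package: trialaudit
Title: Auditing Trial-Averaged Statistics and Chance-Level Claims in
    Yes/No Hemodynamic Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for auditing the statistical analysis of trial-based
    "yes"/"no" hemodynamic (fNIRS HbO) experiments. Implements both
    orders of collapsing trial x session x channel data before a
    timepoint-wise t-test, making explicit which axis supplies the
    replicate variance; a permutation-based validity audit that reruns a
    procedure under shuffled condition labels; per-channel testing; a
    balanced, nested cross-validated linear-SVM decoding pipeline; and
    exact binomial assessment of classification accuracy against chance,
    including the minimum trial count needed for a significant claim. A
    synthetic-data generator emulates correlated-channel hemodynamic
    trial data (double-gamma response, shared and channel-specific
    noise, AR(1) drift) so every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    methods,
    stats,
    utils,
    grDevices,
    jsonlite,
    data.table,
    Rcpp,
    ggplot2,
    rlang
Suggests:
    testthat (>= 3.0.0),
    e1071,
    withr
LinkingTo:
    Rcpp,
    RcppArmadillo
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate:
    'RcppExports.R'
    'utils.R'
    'AllClasses.R'
    'accessors.R'
    'dataio.R'
    'hrf.R'
    'synthetic.R'
    'averaging.R'
    'permutation.R'
    'chance.R'
    'classification.R'
    'pipeline.R'
    'trialaudit-package.R'
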