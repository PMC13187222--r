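Package: scalenet
Title: Network-Based Questionnaire Item Selection and Ordinal Psychometric Validation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for developing and validating short self-report scales from
    ordinal Likert item pools. Implements a five-stage pipeline: item-level
    discrimination statistics and thresholded correlation networks with
    walktrap community detection and multi-strategy item selection;
    exploratory factor analysis for ordinal data (parallel analysis with
    principal axis factoring, oblimin rotation, factorability diagnostics);
    confirmatory factor analysis of polychoric correlations by diagonally
    weighted least squares, with configural/metric/scalar measurement
    invariance testing across groups; ROC-based discriminative validation
    with Youden-optimal thresholds; and a two-group graded-threshold factor
    model simulator so the whole pipeline is testable on synthetic data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    igraph,
    sandwich,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    pracma
Config/testthat/edition: 3
RoxygenNote: 7.3.3
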