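Package: medsift
Title: Screen Scoring and Differentiation Dynamics for Pluripotency Transitions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Statistics for pooled CRISPR reporter screens and embryonic stem
    cell differentiation dynamics. Scores sorted-population guide counts with
    alpha-robust rank aggregation and a permutation false discovery rate,
    applies a compound hit-selection rule across sorting conditions, computes
    signaling-footprint activities and correlations against pathway-defining
    knockouts, estimates differentiation delays against a reference naive-marker
    time course, summarises slopes of regulation and fold-change-ratio modes,
    predicts cell fate from fluorescence traces via ROC analysis with Youden's J,
    gates genotypes with a two-component Gaussian mixture and posterior-certainty
    rule, and counts colonies in clonogenicity-assay images. A synthetic-data
    module generates every input with planted ground truth so the full pipeline
    is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    Matrix,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml,
    zoo,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    pROC,
    mclust,
    withr
Config/testthat/edition: 3
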