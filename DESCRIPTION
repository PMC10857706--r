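Package: omicstack
Title: Late-Fusion Multi-Omics Classification for Alcohol-Associated
    Liver Disease Phenotypes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Classification and biomarker-panel selection workflow for
    three-class liver-disease phenotyping (alcohol-associated hepatitis,
    alcohol-associated cirrhosis, healthy controls) from paired bulk
    transcriptomic and proteomic cohorts. Provides matched/unmatched sample
    partitioning with rebalancing, proteomic missing-value filtering and
    imputation (median or zero, thresholded), filter feature selection by
    per-feature Kruskal-Wallis differential expression with
    Benjamini-Hochberg q-values or by information gain, nested
    cross-validation with in-loop feature selection, hypergeometric
    enrichment scoring of candidate panels, late-fusion stacking of
    per-omics class probabilities into a logistic meta-classifier,
    micro-averaged one-vs-rest ROC/AUC reporting, gene-protein panel
    intersection statistics, and a synthetic multi-omics cohort generator
    for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    nnet,
    e1071,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    fgsea
Config/testthat/edition: 3
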