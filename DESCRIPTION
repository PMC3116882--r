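Package: awasig
Title: Blood Transcriptome Subtype Discovery for Subclinical Atherosclerosis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A tested pipeline for discovering expression-defined molecular
    subtypes in peripheral-blood microarray cohorts and quantifying their
    association with subclinical atherosclerosis. Implements probe filtering
    (coefficient-of-variation and detection-call rules), quantile
    normalization, per-probe differential expression with Storey q-values and
    SAM-style permutation false discovery rates, a multiple-random-validation
    procedure (repeated stratified cross-validation with per-training-set gene
    ranking and support-vector-machine voting) that assigns each sample a
    majority-vote subtype, case-control association statistics (odds ratios,
    sensitivity/specificity, chi-square tests, covariate-adjusted logistic
    regression), average-linkage hierarchical clustering with
    Pearson-correlation distance, cross-study fold-change concordance, and a
    synthetic cohort generator that emulates the statistical structure the
    analysis assumes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    e1071,
    generics,
    ggplot2,
    limma,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
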