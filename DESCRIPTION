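Package: vm4
Title: Four-Type Vaginal Microbiome Classification and Community Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements a dichotomous typing scheme for vaginal microbiome
    (VM) communities that crisscrosses health status (healthy vs. bacterial
    vaginosis) with community structure (complex vs. simple), yielding four
    VM types (HC, HS, BVC, BVS). Provides per-sample diversity and dominance
    metrics (Hill numbers, Lloyd-style mean-crowding community and species
    dominance), K-means dichotomization on a 10-metric feature vector,
    community-level hypothesis tests (shared-species permutation tests,
    Sloan near-neutral model fits, normalized stochasticity ratio, Taylor's
    power-law extension heterogeneity scaling), a species specificity and
    specificity-diversity framework with permutation tests for unique and
    enriched species, a machine-learning reclassification harness over six
    classifier families, and a synthetic cohort generator with planted
    ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    class,
    nnet,
    randomForest,
    e1071,
    xgboost,
    minpack.lm,
    vegan
Suggests:
    biomformat,
    mclust,
    jsonlite,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
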