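Package: frugalpod
Title: Fast-and-Frugal Trees for Perioperative Delirium Risk Stratification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds and evaluates fast-and-frugal decision trees (FFTrees) for
    stratifying older surgical patients by their risk of postoperative
    delirium (POD). Implements the ifan and dfan tree-construction algorithms
    under a balanced-accuracy goal, two balanced-accuracy-targeted comparator
    models (a misclassification-weighted recursive-partitioning tree and a
    base-rate-thresholded logistic regression), a repeated paired 50/50-split
    model-comparison harness, the two published screening trees, and a
    synthetic cohort generator calibrated to the printed characteristics of
    the study cohort.
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
    purrr,
    readr,
    rlang,
    rpart,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
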