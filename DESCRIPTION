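Package: psnmap
Title: Patient Similarity Networks for Outcome Prediction After
    Congenital Heart Surgery
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds clinician-steerable patient similarity networks for
    surgical congenital heart disease cohorts. Pairwise patient distances
    fuse four feature groups - ontology-based diagnosis similarity,
    sparse echocardiographic indicators under three preprocessing schemes
    (original values, z scores, combination ratios), preoperative clinical
    features, and surgical features - with user-adjustable weights.
    Similarity groups (k-nearest-neighbour or threshold) drive
    neighbourhood-vote and locally trained logistic-regression outcome
    predictions, with a full evaluation harness (accuracy, recall,
    precision, F1, rank-based AUC, population-level k selection,
    Mann-Whitney and chi-squared group contrasts), a t-SNE map layout for
    cohort visualisation, and a seeded synthetic cohort generator so the
    whole pipeline is testable without clinical data.
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
    glmnet,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    knitr,
    optparse,
    pROC,
    readr,
    rmarkdown,
    testthat (>= 3.0.0)
VignetteBuilder: knitr
Config/testthat/edition: 3
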