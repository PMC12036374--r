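Package: rapidprog
Title: Predicting Rapid Cognitive Decline from Electronic Health Record Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for identifying rapid progression of Alzheimer's disease and
    related dementias from mixed structured/unstructured electronic health
    records. Extracts MMSE and MoCA scores from clinical-note text with a
    documented, extensible pattern bank; applies cohort exclusion rules and
    labels patients by cognitive decline rate (points per year); preprocesses
    and selects structured features (min-max scaling, one-hot encoding,
    missingness filtering, variance/correlation/chi-squared/ANOVA rules, KNN
    imputation); rebalances imbalanced training sets with a hybrid
    clustering- and cosine-similarity-based duplication sampler alongside
    standard comparators; trains an autoencoder-based classifier with a joint
    focal/reconstruction loss; combines two instrument-specific models with a
    stacked logistic ensemble; and explains predictions with additive
    per-feature attributions satisfying a local-accuracy contract. A
    reproducible synthetic-cohort generator makes the whole pipeline testable
    without access to protected health data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
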