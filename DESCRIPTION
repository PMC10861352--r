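Package: sispanel
Title: Sure-Independence Screening and Biomarker Panel Selection for
    Case-Control Proteomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for preoperative plasma biomarker discovery
    in ultra-high-dimensional (p >> n) case-control proteomic studies:
    per-marker volcano statistics (Welch t, Kolmogorov-Smirnov and
    Mann-Whitney tests with log2 fold changes), consensus sure-independence
    screening across the three tests, lasso-penalized logistic panel
    selection with backward AIC refinement, per-marker empirical ROC/AUC
    and Youden-index cutoffs, and leave-one-out cross-validated panel
    accuracy. Includes a synthetic case-control cohort generator with
    planted differential markers so the full pipeline is reproducible
    without access to patient-level data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    glmnet,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    MASS,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
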