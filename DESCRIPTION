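Package: starmh
Title: Psychometric Derivation and Validation of the STAR-MH Mental Health Screen
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to derive and validate a brief dichotomous mental-health
    screening scale of the STAR-MH type (two immediate screen-in items plus a
    short summed scale) against a structured-interview reference diagnosis.
    Implements the item-selection cascade (per-item sensitivity/specificity and
    kappa filters, Spearman/accuracy filters, CART retention, endorsement
    specificity curves), scale scoring with early-exit screen-in logic,
    conditional maximum likelihood estimation of the dichotomous Rasch model
    with infit/outfit statistics and person-separation reliability,
    unidimensionality testing by modified parallel analysis on tetrachoric
    correlations, Ponocny's T1 quasi-exact test for local dependence via
    fixed-margin matrix sampling, logistic-regression differential item
    functioning with Nagelkerke R-squared effect sizes, and diagnostic-accuracy
    evaluation (ROC, DeLong intervals, bootstrap optimism correction, Youden
    cutoff selection, likelihood-ratio and predictive-value tables). A
    Rasch-based cohort simulator reproduces the statistical structure of the
    validation study so that every stage can be exercised end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    jsonlite,
    rpart,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
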