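Package: camimc
Title: CAM-IMC Delirium Screening and Diagnostic Test Accuracy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Scores the Confusion Assessment Method for the Intermediate Care
    Unit (CAM-IMC), a ten-point bedside screen for postoperative delirium in
    non-intubated patients that combines fluctuating mental status, altered
    level of consciousness (RASS != 0), a ten-letter inattention task and a
    five-dimension verbal disorientation test, positive at three points or
    more. Provides the diagnostic-accuracy toolkit used to evaluate such
    instruments against a reference diagnosis: exact Clopper-Pearson intervals
    for sensitivity, specificity and predictive values, likelihood ratios with
    log-method intervals, ROC curves and AUROC with DeLong variance, Youden
    cut-off selection, and Cohen's kappa for interrater reliability. A
    calibrated synthetic-cohort simulator generates observation-level
    assessment data with configurable prevalence, item operating
    characteristics and rater agreement so the whole pipeline is testable
    without patient data.
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
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    e1071,
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
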