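Package: cecdx
Title: Diagnostic Accuracy of Circulating Endometrial Cells Without a
    Gold Standard
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Evaluates diagnostic tests for endometriosis when no perfect
    reference standard exists. Implements a constrained two-class latent
    class (Hui-Walter) model for a panel of binary tests fit by an EM
    algorithm, kernel-weighted local-likelihood extensions in which
    prevalence and test accuracies vary smoothly with pain scores within
    menstrual-cycle phase strata, imputation-based pooled accuracy
    estimation, and percentile bootstrap confidence intervals. Includes a
    synthetic patient-level cohort generator matching the assumed model
    structure (hurdle count model for circulating endometrial cell counts,
    cell-size subtype mixtures, treatment effects) and the descriptive
    layer of detection rates and stratified summaries.
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
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
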