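Package: stretchsig
Title: Discovery and Validation of Mechanical-Stretch Transcriptomic Signatures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Pools multi-study expression data with control-anchored empirical-Bayes
    batch co-normalization, identifies features responding to cyclic mechanical
    stretch under a two-factor (stretch + second-hit) linear model with
    Benjamini-Hochberg false-discovery control, computes geometric-mean-difference
    transcriptomic scores, refines signatures by greedy forward selection
    maximizing the area under the ROC curve, and validates them with bootstrap
    confidence intervals, random-signature null distributions, leave-one-study-out
    analysis and dose-response correlation. Includes a synthetic multi-study data
    generator with planted batch effects, signatures and dose-response structure
    for end-to-end testing of the workflow.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    generics,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
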