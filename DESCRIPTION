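Package: oscillab
Title: Forced Oscillation Technique Respiratory Impedance Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis pipeline for forced oscillation technique
    (FOT) lung-function testing. Provides forward mechanical models of
    respiratory impedance (resistor, RIC, extended-RIC, two-compartment),
    synthesis of multisine pressure-flow records superimposed on spontaneous
    breathing, Welch cross-spectral impedance estimation with coherence-based
    quality control, extraction of the eight classical oscillometry parameters
    (R0, Rm, R4, S, Xm, fr, Cdyn, Z4), cohort group comparisons and correlation
    analysis with a modified Bonferroni correction, ROC diagnostic-accuracy
    analysis with Youden optimal cut-offs and Hanley-McNeil sample-size
    calculations, and a machine-learning decision-support layer with
    cross-validated classifiers and exhaustive feature-subset search.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    purrr,
    tidyr,
    rlang,
    ggplot2,
    generics,
    withr,
    jsonlite,
    yaml,
    readr,
    stats,
    utils,
    e1071,
    randomForest,
    rpart,
    class
Suggests:
    testthat (>= 3.0.0),
    pROC,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
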