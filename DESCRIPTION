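Package: ntcppce
Title: NTCP Modelling of Radiation-Induced Pericardial Effusion
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Normal tissue complication probability (NTCP) modelling of
    pericardial effusion after thoracic chemoradiotherapy. Implements
    dose-volume histogram (DVH) handling and dose metrics, the generalised
    equivalent uniform dose (gEUD), Lyman-Kutcher-Burman (LKB) and mean heart
    dose (MHD) based probit dose-response models, logistic NTCP models with
    clinical covariates, maximum-likelihood parameter estimation, tolerance
    dose (TD) inversion, and TRIPOD-style internal validation (bootstrap
    optimism-corrected AUC, Hosmer-Lemeshow calibration). A synthetic cohort
    generator reproduces the statistical structure of a definitive
    chemoradiotherapy oesophageal cancer cohort so the whole pipeline is
    testable without patient data.
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
    jsonlite,
    readr,
    withr,
    generics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
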