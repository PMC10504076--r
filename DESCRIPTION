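Package: hfpeftrial
Title: Obesity-Class Subgroup Analysis Pipeline for Weight-Loss Trials in HFpEF
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Participant-level analysis pipeline for randomized weight-loss
    trials in heart failure with preserved ejection fraction (HFpEF),
    stratified by obesity class. Implements the hierarchical-composite win
    ratio with Cochran's Q heterogeneity test across body-mass-index classes,
    ANCOVA-based multiple imputation with Rubin's-rule pooling (including the
    multivariate combination behind the treatment-by-subgroup interaction
    F-test), Jonckheere-Terpstra, Cochran-Armitage and score-based
    Cochran-Mantel-Haenszel baseline trend tests, and weight-loss
    dose-response regressions (continuous per-10-percent-loss slopes and
    ordinal category analyses with a linearity F-test). A seeded
    synthetic-trial generator emulates the statistical structure such trials
    assume, so every stage is testable without access to participant-level
    trial data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    tools,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
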