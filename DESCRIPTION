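Package: behavcast
Title: Next-Day Forecasting of Seizures and High-Risk Behaviors from Daily
    Behavior Diaries
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Per-subject forecasting of next-day seizure episodes and
    high-risk behaviors (aggression, self-injurious behavior, elopement)
    from 7- or 14-day windows of daily binary behavior vectors derived
    from shift-level care diaries. Implements the full analysis pipeline:
    top-7-plus-Other category mapping and daily binarization, sliding
    windows with next-day labels, a small per-subject two-block 2-D
    convolutional network trained natively in R, a prevalence-aware
    permutation significance test with its closed-form null mean and the
    delta-accuracy effect size, first-layer Grad-CAM feature attribution,
    and a synthetic behavior-diary cohort generator with known ground
    truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    rlang,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
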