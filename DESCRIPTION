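Package: hrvreact
Title: Heart Rate Variability Reactivity Analysis for Early Cardiotoxicity Screening
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools to quantify cardiac autonomic reactivity from beat-to-beat
    RR-interval recordings acquired under a three-condition protocol (supine
    rest, active standing, paced breathing at 0.1 Hz) and to evaluate
    reactivity deltas as predictors of early chemotherapy-related cardiac
    dysfunction. Provides NN-interval cleaning and stable-segment selection,
    time-domain (mean NN/HR, SDNN, pNN50), spectral (Welch periodogram LF/HF
    band powers, normalized units, log10 LF/HF) and Poincare (SD1, SD2)
    indexes, per-subject condition deltas, ROC analysis with the
    closest-to-(0,1) cut-off rule and Hanley-McNeil inference, cohort
    statistics (normality-gated log transform, t-tests, repeated-measures
    ANOVA, categorical tests, Pearson correlation panels), left-atrial strain
    reduction and cardiotoxicity classification rules, and a fully synthetic
    cohort generator that emulates the study design for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    pROC,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
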