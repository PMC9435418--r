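Package: noisecare
Title: Bayesian Network Modelling of Hospital Noise Exposure and Quality of Patient Care
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to analyse the effect of occupational hospital noise on the
    quality of patient care delivered by nursing staff. Implements ISO 9612
    style computation of equivalent continuous sound pressure levels and the
    daily personal noise exposure level (LEP,d) from repeated point
    measurements and workstation assignments; scoring and categorisation of
    the Weinstein noise-sensitivity scale, a 100-point annoyance visual
    analogue scale and a 65-item quality-of-patient-care scale (with
    Cronbach's alpha and EM-based item imputation); a discrete Bayesian
    network engine with exact inference by variable elimination, EM parameter
    learning from incomplete categorical records, delta-p evidence
    sensitivity analysis and arc influence values; k-fold cross-validated
    classification with confusion-matrix metrics and one-vs-rest ROC/AUC; and
    a synthetic cohort generator so the full pipeline can be exercised and
    tested without access to the original survey data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
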