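Package: querysift
Title: Screening for Gynaecological Malignancy from Pre-Referral Online
    Search Histories
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for case-control classification of
    symptomatic patients (malignant versus benign gynaecological diagnosis)
    from their timestamped online search histories in the months before an
    urgent-cancer-pathway referral. Implements a two-stage health filter
    over raw query logs, assignment of queries to curated symptom
    categories, outcome-stratified weekly query timelines, time-window
    bag-of-words and category featurization, gradient-boosted
    leave-one-out-cross-validated classification with a sample-size
    corrected AUC, health-engagement filtering, questionnaire association
    tests, scoring of external control populations, and a synthetic cohort
    generator so that every stage can be exercised and tested without
    access to patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    rlang,
    stats,
    stringi,
    tibble,
    tidyr,
    utils,
    xgboost,
    yaml
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
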