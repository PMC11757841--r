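Package: boosterdd
Title: Delay Discounting Titration and Multilevel Modelling of COVID-19 Booster Willingness
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Implements an adjusting-amount delay-discounting titration task
    with area-under-the-curve (AuC) scoring, questionnaire scoring (GAD-7,
    PHQ-9, IUS-12) with a standardized psychological distress index, sample
    exclusion and response coding rules, an inter-rater agreement utility,
    and a country-nested random-intercept logistic regression predicting
    booster willingness. A synthetic-cohort generator runs simulated
    discounting agents through the actual titration engine and draws binary
    outcomes from a multilevel logistic model, so the whole pipeline is
    testable end-to-end by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    lme4,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pracma,
    e1071,
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
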