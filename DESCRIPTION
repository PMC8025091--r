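Package: npmcompare
Title: Compare Nutrient Profiling Models for Front-of-Package Warning Labels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Rule-based classification of packaged foods under the nutrient
    profiling models used or proposed for front-of-package (FOP) warning
    labels in Latin America: the PAHO model (nutrient-to-energy ratios with
    NOVA-based eligibility), the Chilean Law 20.606 model (per-100 g/ml
    thresholds with added-ingredient eligibility and the culinary-ingredient
    rule), the model proposed by the Brazilian agency Anvisa, and a modified
    PAHO model with Chilean eligibility. Includes keyword-based detection of
    added sugar, salt, fat and non-nutritive sweeteners in Portuguese
    ingredient lists, free-sugar estimation from declared sugars,
    database-cleaning filters and reconstitution to as-consumed form,
    strictness and agreement statistics (proportions with Wald confidence
    intervals, cross-classification, Cohen's kappa with interpretation
    bands), and a synthetic food-supply generator with planted ground truth
    for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    readr,
    rlang,
    stats,
    stringi,
    tibble,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
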