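Package: effortrisk
Title: Consumer Effort-Risk Scoring from Health Insurance Claims
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies the administrative effort that health-care consumers
    (households on one insurance plan) expend in finding and paying for care.
    From a 12-month claims extract and contact-center event log, the package
    counts six expert-elicited effort factors per household (household members
    with claims, out-of-network visits, claim adjustments, claim denials,
    phone inquiries, and web or mobile inquiries), restricts analysis to the
    diagnosis codes that jointly cover a configurable share of all diagnosis
    occurrences, averages each factor per diagnosis, applies expert
    percentage weights to produce a composite effort-risk score, and ranks
    diagnoses by that score. A seeded synthetic-claims generator with
    closed-form ground truth supports end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
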