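Package: cusumlc
Title: CUSUM Learning Curves for Procedural Competency Assessment
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for assessing procedural competency from sequences of
    binary attempt outcomes using cumulative-failure (CUSUM) control charts
    with boundaries derived from Wald's sequential probability ratio test.
    Computes acceptable/unacceptable control lines from design failure rates
    and error rates, classifies trainees by first boundary crossing, compares
    cohorts via odds ratios, logistic regression and Welch t-tests, runs
    sensitivity analyses over failure-rate settings, and simulates trainee
    learning with declining failure probability for operating-characteristic
    and power studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
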