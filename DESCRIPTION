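Package: crosswise
Title: Prevalence Estimation and Individual-Level Validation for the
    Crosswise Model
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Estimation of the prevalence of sensitive attributes from
    crosswise-model (CWM) and direct-questioning (DQ) surveys, with
    maximum-likelihood fitting of the underlying multinomial processing
    trees by expectation maximization, delta-method standard errors,
    G-squared likelihood-ratio tests of parameter restrictions across
    conditions, and individual-level validity analysis (false-positive
    and false-negative rates on criterion-split subsamples, with
    moderator comparisons). Includes a synthetic-respondent generator
    emulating an anagram-cheating validation design, design utilities
    (variance-based allocation ratios, Wald power for two-condition
    comparisons), and an end-to-end study pipeline from respondent-level
    CSV data to a structured report.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
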