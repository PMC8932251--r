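Package: veribias
Title: Verification-Bias-Adjusted Accuracy of Multiple Screening Tests
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Estimates sensitivity, specificity, positive and negative
    predictive value of K binary screening tests when receipt of the
    reference standard depends on the screening results (verification
    bias). Implements complete-case analysis with exact binomial
    intervals, the Begg-Greenes allocation estimator generalized to
    2^K screening-result strata with bootstrap confidence intervals,
    and multiple imputation of missing disease status from a logistic
    disease model (maximum-likelihood or Firth-penalized) pooled by
    Rubin's rules with Wilson intervals on an effective sample size.
    Includes a synthetic screening-study simulator with a
    missing-at-random verification mechanism for parameter-recovery
    and coverage studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
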