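Package: sipw
Title: Partial Verification Bias Correction for Binary Diagnostic Tests
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Corrects partial verification bias in estimates of sensitivity
    and specificity of binary diagnostic tests when disease status is
    verified only for a test-dependent subset of patients (missing at
    random). Implements scaled inverse probability weighted resampling
    (SIPW) and its class-balanced variant (SIPW-B), alongside the inverse
    probability bootstrap (IPB), Begg-Greenes correction, inverse
    probability weighting estimator, multiple imputation, complete case
    and full data analysis. Includes a multinomial simulation engine with
    validity screening, a Monte Carlo study harness reporting bias and
    standard error, and Wald, bootstrap percentile and Rubin's rules
    confidence intervals.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    MASS,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
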