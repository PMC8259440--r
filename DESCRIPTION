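Package: noncollapse
Title: Separating Confounding Bias from Noncollapsibility in Logistic Regression
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools to quantify how much of the change in an exposure
    coefficient between univariable and multivariable logistic regression
    reflects genuine confounding bias and how much is the noncollapsibility
    effect of the odds ratio. Provides three exposure-effect estimators
    (univariable, multivariable, inverse-probability-weighted via a
    propensity score, plus G-computation standardization), the decomposition
    of the change in estimate into confounding bias and a noncollapsibility
    effect with percentile-bootstrap confidence intervals, large-sample
    limits of all three estimands by Gauss-Hermite quadrature, a
    synthetic-cohort generator, and a factorial Monte Carlo study runner
    that reproduces the sign and monotonicity patterns of the two components.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    sandwich,
    pracma
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
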