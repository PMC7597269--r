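Package: fbsts
Title: Full Bayesian Significance Tests for Unit Roots and Cointegration
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Bayesian e-value tests for stochastic trends in time series.
    Implements the Full Bayesian Significance Test (FBST) for the unit-root
    hypothesis in AR(p) models written in augmented Dickey-Fuller form, and
    for the cointegration rank of vector error-correction models (VECM) via
    a Johansen-style reduced-rank posterior maximization. Evidence values
    are computed by Gibbs sampling from Normal-Inverse-Gamma (univariate)
    and matrix-normal-Inverse-Wishart (multivariate) posteriors under flat
    and Jeffreys-type improper priors. Includes the asymptotic chi-square
    calibration between e-values and likelihood-ratio p-values, seeded
    generators for AR and cointegrated VECM data with known truth, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    rlang,
    generics,
    ggplot2,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
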