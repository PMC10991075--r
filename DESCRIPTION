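Package: cencorr
Title: Correlation Estimation for Doubly Censored Bivariate Normal Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for understanding and correcting the distortion that
    left and right censoring (floor effects, ceiling effects, limits of
    detection) induces in Pearson correlations.  Provides the analytic
    attenuation of a latent bivariate-normal correlation under arbitrary
    censoring schemes, a seeded Monte-Carlo censoring simulator, a
    full-information maximum-likelihood estimator of the latent
    correlation from doubly censored data with Wald and
    profile-likelihood confidence intervals, and a simulation-study
    harness that evaluates bias, root mean square error, coverage and
    interval width over grids of correlations, censoring patterns and
    sample sizes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
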