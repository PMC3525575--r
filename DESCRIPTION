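Package: twinlim
Title: Sex-Limitation Twin Models for Qualitative and Quantitative Sex
    Differences in Genetic Architecture
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Maximum-likelihood saturated and ACE sex-limitation models for
    twin data across the five zygosity-by-sex groups (MZM, MZF, DZM, DZF and
    opposite-sex DZ pairs). Fits continuous phenotypes by bivariate-normal
    likelihood and ordinal phenotypes by a liability-threshold model with
    polychoric correlations, with age or birth-cohort regressed on means or
    thresholds. Provides the nested likelihood-ratio testing ladder used to
    screen traits for sex differences in genetic architecture, estimation of
    the opposite-sex genetic correlation (gamma) and shared-environment
    correlation (phi), a noncentral chi-square power calculator for the
    DZ same-sex versus opposite-sex correlation contrast, and a simulator
    that generates twin pairs with the exact ACE covariance structure the
    models assume.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    pracma
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
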