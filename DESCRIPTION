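Package: twinclpm
Title: Biometric Cross-Lagged Twin Models for Longitudinal Psychopathology
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and estimation tools for studying the longitudinal
    interplay between a general psychopathology (p) factor and child-rated
    home environment in twin cohorts.  Provides a component-level
    (additive-genetic / shared-environment / nonshared-environment)
    cross-lagged generating model for three-wave twin data with known
    ground truth, data preparation (age/sex residualization, composite
    scoring, one-twin-per-pair selection), single-factor confirmatory
    factor analysis with full-information maximum likelihood, phenotypic
    cross-lagged panel models with bootstrap confidence intervals,
    univariate and cross-lagged ACE twin models with A/C/E path
    decomposition, and the MZ-differences design.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: stats, utils, jsonlite, yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
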