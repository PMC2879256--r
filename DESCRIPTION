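Package: bodycomp
Title: Fat-Free Mass - Fat Mass Models for Body-Composition Prediction and
    Energy-Balance Coupling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for modelling the cross-sectional relationship between
    fat-free mass (FFM) and fat mass (FM) in adults. Implements a class of
    fourth-order FFM-FM polynomials with age, height, sex and race as
    covariates (developed from the NHANES 1999-2004 DXA reference
    population), together with the classical Forbes log-linear FFM-FM
    curves and their vertically translated family. Supports inversion of
    the mass-balance identity (total mass = FM + FFM) by bracketed root
    finding to recover body composition from body weight, prediction of
    longitudinal FFM change under weight change, zero-fat minimal-BMI
    curves as a function of height and age, refitting of the polynomial
    class to cohort data with significance screening, a synthetic-cohort
    generator, and coupling of the FFM model to a one-dimensional
    energy-balance differential equation integrated with a classical
    fixed-step fourth-order scheme. A command line interface exposes the
    main operations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    deSolve,
    knitr,
    rmarkdown
Config/testthat/edition: 3
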