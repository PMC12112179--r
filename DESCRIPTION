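Package: agestage
Title: Age-Stage Two-Sex Life Tables, Bootstrap Inference, and Probit
    Dose-Mortality Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Tools for cohort-based insect demography and insecticide
    bioassay analysis.  Implements the age-stage, two-sex life table
    (age-stage survival, fecundity, life expectancy and reproductive
    value, with population parameters R0, r, lambda, T and GRR via the
    Euler-Lotka equation), bootstrap standard errors and paired
    bootstrap tests between strains, relative fitness, Pearson
    correlation of life-table parameters with selection generation,
    probit dose-mortality models with Fieller/fiducial confidence
    limits for lethal concentrations and resistance ratios, and
    stage-structured synthetic cohort and bioassay generators with
    closed-form expected parameters for recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
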