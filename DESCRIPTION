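Package: selmosaic
Title: Phenotypic Selection Analysis for Paired Crop-Proximity Field Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for estimating and comparing natural selection across
    replicated paired plant populations planted near versus far from a crop
    relative. Implements Lande-Arnold phenotypic selection analysis (selection
    differentials and gradients with collinearity diagnostics), mixed-model
    ANCOVA tests for proximity-dependent selection, variance-ratio tests for
    homogeneity of selection across populations, and multigroup piecewise
    structural equation models linking floral traits, pollinator and
    seed-predator activity, and fitness. A synthetic-data generator emulates
    the paired near/far design with correlated traits, interactor-mediated
    fitness and known ground-truth gradients so every stage is testable
    without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    MASS,
    car,
    graphics,
    jsonlite,
    lme4,
    lmerTest,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
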