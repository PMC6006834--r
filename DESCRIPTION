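Package: realistsem
Title: Structural Equation Modelling of Realist Context-Mechanism-Outcome
    Configurations
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Quantitative exploration of realist context-mechanism-outcome
    (CMO) configurations with structural equation models. Compiles CMO
    declarations and measurement models (reflective latents, a formative
    composite, categorical contexts expanded to dummies) into a single
    recursive covariance-structure model, fits it by maximum likelihood with
    naive and cluster-robust (sandwich) standard errors, standardizes
    estimates, decomposes each CMO into direct and indirect effects with
    delta-method intervals and proportion mediated, and assesses fit with
    RMSEA, CFI and TLI against an independence baseline. Includes a
    two-level synthetic data generator emulating linked individual-level and
    practice-level survey data so the whole pipeline is testable without
    access to restricted microdata.
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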