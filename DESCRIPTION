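Package: metsem
Title: Sleep-Mediated Metabolic Syndrome Severity Analysis by Structural
    Equation Modelling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A reproducible pipeline for studying how habitual sleep duration
    mediates the effects of age, socioeconomic status, physical activity,
    obesity, sleep latency, nap duration and night-shift work on continuous
    metabolic syndrome (MetS) severity in adult cohorts. Provides cohort
    ingestion with an auditable exclusion cascade, sex-specific continuous
    MetS severity scoring, a principal-component wealth index with tertile
    grouping, skewness/kurtosis normality screening, a maximum-likelihood
    structural equation engine (RAM parameterization, analytic gradients,
    latent obesity measurement model), direct/indirect/total effect
    decomposition with bootstrap inference, and a synthetic-cohort generator
    for end-to-end validation and parameter-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    MASS,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
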