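Package: emodyn
Title: Emotion Dynamics from Intensive Longitudinal Assessments
Version: 0.1.0
Authors@R: person("UAS", "Methods Lab", email = "methods@example.org", role = c("aut", "cre"))
Description: Computes person-level measures of intraindividual emotion
    dynamics (mean level, variability, instability, inertia, network
    density, mixed emotions, dialecticism) from three intensive
    longitudinal assessment designs: ecological momentary assessment,
    end-of-day diaries, and the day reconstruction method. Provides a
    multilevel estimation engine returning empirical-Bayes person
    coefficients, a cross-method comparability analysis (repeated-measures
    ANOVA, dependent-correlation Wald tests, correlation networks with
    node strength, health-outcome associations), and a calibrated
    synthetic-study generator built on a person-specific bivariate
    vector-autoregressive latent affect process.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    lme4,
    Matrix,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
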