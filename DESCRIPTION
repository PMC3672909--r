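Package: cdvar
Title: Within-Person Variability and Determinants of Urinary Cadmium
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for studying the reliability of urinary cadmium (U-Cd)
    as an exposure biomarker from repeat 24-hr urine collections, and for
    identifying its determinants. Provides a seeded synthetic-cohort
    generator (participants, repeat urine samples, food-frequency
    responses, and planar geographic layers), biomarker preprocessing
    (limit-of-detection substitution, creatinine adjustment, daily output,
    geometric-mean summaries), GIS-style exposure metrics (traffic density
    within a residential buffer, industrial emissions within a radius,
    tract-linked air concentrations, dietary cadmium from a food-frequency
    questionnaire), REML variance-components estimation of within- and
    between-person variance, the intraclass correlation, and the variance
    ratio, analytic and simulation-based propagation of biomarker
    measurement error to case-control odds-ratio attenuation, and
    random-intercept mixed models with backward elimination,
    percent-change reporting, cumulative R-squared, and 10-fold
    cross-validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    lme4,
    jsonlite,
    stats,
    graphics,
    utils,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
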