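Package: pris
Title: Predictive Response to Immunotherapy Score for Sublingual Immunotherapy Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for computing the Predictive Response to Immunotherapy
    Score (PRIS), an eight-parameter clinical point score (range 20-100)
    used to predict symptom improvement under sublingual allergen
    immunotherapy (SLIT), together with the full validation workflow:
    eligibility screening of allergic-rhinitis patients, dominant-allergen
    identification from skin prick tests and specific IgE, visual-analogue
    scale (VAS) symptom indices (mean symptom score and its percentage
    change), quartile stratification of score and response, the associated
    statistical battery (Pearson-correlation power analysis,
    repeated-measures and one-way ANOVA, linear and per-parameter
    regression), and a seeded synthetic-cohort generator calibrated to
    realistic cohort descriptive statistics so the whole pipeline is
    testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
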