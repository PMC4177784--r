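Package: lipidecay
Title: Storage-Time Decay of Serum Lipoproteins and Its Impact on
    Cardiovascular Risk Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying the slow decay of total and HDL
    cholesterol in long-term frozen serum samples and for assessing its
    clinical consequences. Provides a synthetic inception-cohort
    simulator with staircase storage design, random-intercept
    longitudinal models with period-effect testing and change-in-estimate
    confounder screening, a linear storage-decay correction factor,
    Friedewald LDL calculation, the SCORE Weibull 10-year fatal
    cardiovascular risk model (total-cholesterol and TC:HDL-ratio
    variants), and before/after risk reclassification tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools
Suggests:
    lme4,
    testthat (>= 3.0.0),
    jsonlite,
    knitr
Config/testthat/edition: 3
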