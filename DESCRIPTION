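Package: intervmed
Title: Interventional Disparity Mediation Analysis for Stroke Outcomes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Decomposes socioeconomic disparities in death or dependency after
    ischemic stroke into interventional disparity direct and indirect effects
    through grouped binary mediators (comorbidities and medications, stroke
    severity, reperfusion therapy, stroke-unit care). Effects are estimated by
    Monte-Carlo g-computation over fitted logistic outcome and sequential
    mediator models with common random numbers, with an exact enumeration
    oracle, nonparametric bootstrap standard errors, multiple imputation of a
    partially missing severity mediator pooled by Rubin's rules, and a
    calibrated synthetic stroke-registry generator with enumerable ground
    truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
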