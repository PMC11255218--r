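Package: ovoscope
Title: Embryo Respirometry, Thermal Metabolic Scope, Growth and Expression
    Profiling for Cephalopod Development
Version: 0.1.0
Authors@R:
    person("Ovoscope", "Developers", email = "ovoscope@example.org",
           role = c("aut", "cre"))
Description: Tools for the quantitative analysis of octopus embryo
    development: closed-chamber micro-respirometry (linear-segment slope
    estimation, blank correction, the MO2 equation, Q10), thermal metabolic
    scope from temperature-induced metabolic rates (TIMR min/max) smoothed
    with loess over embryo wet weight, exponential stage-weight growth models
    with inverse prediction of early-stage embryo weights, oxidative-stress
    biomarker stage profiles with bootstrap fold-ratios, and
    efficiency-corrected qPCR relative expression (standard-curve
    efficiencies, reference-gene stability ranking, Hellemans normalization).
    Includes a seeded synthetic-data generator that emulates every pipeline
    input with known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
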