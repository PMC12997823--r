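Package: rsfscales
Title: Multi-Scale Resource Selection Analysis for GPS-Tracked Ungulates
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for hypothesis-driven resource selection analysis of
    stationary prey species tracked by GPS telemetry. Implements derivation of
    habitat covariates on a common 30 m grid (focal Shannon diversity, terrain
    ruggedness, proximity to water), two-level use-availability sampling
    (landscape and home-range order selection), binomial mixed-model fitting of
    named hypothesis sets with AIC contrasts and the delta-AIC-ratio support
    statistic, k-fold cross-validation of fitted selection functions via
    area-adjusted frequency rank correlations, hourly split models with
    raised-cosine diel regression, lunar-interaction extraction, and an
    individual-level functional-response test. A synthetic landscape and track
    generator with known ground-truth selection coefficients makes every stage
    testable by parameter recovery without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    lme4,
    jsonlite,
    yaml,
    stats,
    utils,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    knitr
Config/testthat/edition: 3
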