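Package: vlur
Title: Visual Land Use Regression for Mobile Air-Quality Monitoring
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building hyperlocal air-pollution surfaces from mobile
    monitoring campaigns and street-view-derived visual features. Implements
    the full pipeline: preprocessing of 1 Hz drive-by measurements (plausibility
    filtering, winsorization, reference-site temporal correction, snapping to a
    50 m road-segment network, drive-pass construction and mean-of-means
    aggregation), assignment and temporal selection of street-view panoramas,
    assembly of classic buffer-based and visual predictor matrices with
    direction priors, direction-constrained supervised stepwise linear
    regression and tuned random-forest land use regression, seasonal model
    averaging, cross-validated and external fixed-site evaluation, and
    Shapley-based attribution of model importance to street-view features. A
    synthetic-data module generates every pipeline input with known ground
    truth for validation and parameter-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    ranger,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    knitr,
    withr
Config/testthat/edition: 3
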