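Package: hcindex
Title: Wealth-Related Inequality in Binary Health Indicators
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Measures and decomposes socioeconomic inequality in binary
    health indicators from complex household surveys.  Provides weighted
    fractional ranks, concentration curves, the Erreygers concentration
    index for bounded outcomes, and a Wagstaff-type decomposition of the
    index into covariate contributions based on a weighted logit model and
    average marginal effects.  Includes an asset-based wealth index (first
    principal component of household assets with weighted quintile groups),
    stratified cluster-bootstrap uncertainty, trend summaries of an index
    across survey rounds, and a generator of DHS-like two-stage clustered
    survey data with known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
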