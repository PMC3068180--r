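Package: nichecast
Title: Maximum-Entropy Niche Models and Climate-Change Range Projection
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Fits maximum-entropy (MaxEnt-style) presence-background species
    distribution models with linear, quadratic and hinge features, evaluates
    them with presence-background ROC/AUC, cross-validation replicates and
    null-model randomisation tests, and projects habitat suitability under
    climate-change scenarios with equal-weight consensus forecasts. Includes
    range-change analysis (gain, loss, retained cells, species turnover,
    latitudinal shift), derivation of bioclimatic predictors from monthly
    climate layers, collinearity screening, grid-based occurrence
    deduplication, and a synthetic-landscape generator with a known
    suitability truth for end-to-end validation. Gridded layers are handled
    as ESRI ASCII grids on a regular longitude-latitude lattice.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
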