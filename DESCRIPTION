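Package: reedgrid
Title: Cellular Analysis and Boosted-Tree Habitat Modelling of Coastal Reed Spread
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing the occurrence and spread of the common reed
    (Phragmites australis) in shallow coastal waters on a cellular data model.
    Provides a light raster grid engine (polygon rasterization, patch shape
    metrics, wave-fetch openness, distance and land-cover predictor grids), a
    synthetic coastal landscape and occupancy-dynamics generator with known
    ground truth, conditioned Latin hypercube sampling of cell frames,
    exponential growth-rate accounting between occupancy snapshots, multi-scale
    neighborhood state-transition analysis, stochastic gradient boosted
    regression trees with Bernoulli deviance for habitat suitability, and
    ROC/threshold based map evaluation for interpolation and extrapolation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    pracma,
    yaml,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    xgboost,
    ggplot2
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
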