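Package: snakerisk
Title: Geostatistical Estimation and Mapping of Household Snakebite Risk
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Model-based geostatistics for binary household survey outcomes
    such as snakebite. Fits a hierarchical Bayesian logistic model with a
    Matern (nu = 1) spatially correlated random effect by Laplace
    approximation with grid integration over the field hyperparameters,
    runs an iterative covariate-selection procedure (Pearson correlation
    filter, sequential variance inflation factors, negligible-effect
    pruning, WAIC comparison, interaction checks, spatial ablation),
    predicts risk on a regular kilometre grid, and aggregates population
    at risk by administrative unit. Includes a synthetic-survey generator
    with clustered households, smooth environmental surfaces and a latent
    Gaussian random field so the whole pipeline is testable end to end,
    plus plain-text geospatial input/output (CSV point tables, ESRI ASCII
    grid rasters, GeoJSON vector layers).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, jsonlite, yaml
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
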