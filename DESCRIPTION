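Package: edumap
Title: Model-Based Geostatistical Mapping of Educational Attainment
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Desk-scale Bayesian model-based geostatistics for mapping
    educational-attainment indicators (mean years of schooling and four
    ordinal attainment bins) over a pixel grid and time. Implements a
    continuation-ratio decomposition of the ordinal bins into conditional
    binomials, a stacked-ensemble mean function (additive splines, boosted
    trees, L1-penalized regression), a Matern-by-AR1 Kronecker space-time
    Gaussian process with country random effects and a nugget, fitting by
    penalized MAP with a Laplace-approximate posterior and nested
    hyperparameter optimization, posterior field draws, population-weighted
    aggregation to administrative units, ratio raking to national reference
    estimates, masking, inequality metrics (index of dissimilarity, additive
    decomposition of national change, gender-parity exceedance), and
    source-stratified cross-validation diagnostics. Includes a synthetic-world
    generator that emulates geolocated survey inputs so the whole pipeline is
    testable without restricted data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    mgcv,
    glmnet,
    xgboost
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
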