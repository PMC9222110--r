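Package: sdmcompare
Title: Ensemble Species Distribution Models Under Contrasting Sampling Frameworks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds consensus (0-5) ensemble species distribution models from five
    algorithms (logistic regression, boosted regression trees, random forests,
    multivariate adaptive regression splines, and a maximum-entropy-equivalent
    penalized logistic model) trained on either designed presence/absence surveys
    or presence-only convenience samples with background points, and quantifies
    the agreement of the resulting consensus maps with areal cross-tabulations,
    Cohen's (weighted) kappa with Fleiss standard errors, and omission-error
    classification. Includes a lightweight raster data model with ESRI ASCII grid
    input/output, computation of the 19 bioclimatic variables from monthly
    climate, and a synthetic-landscape generator that emulates stratified
    transect surveys and spatially biased, positionally erroneous convenience
    sampling so the whole pipeline runs end-to-end without external data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    glmnet,
    ranger,
    xgboost,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    tiff,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
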