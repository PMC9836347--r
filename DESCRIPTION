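Package: tppr
Title: Temporal Phenomic Prediction for Plant Breeding Trials
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for temporal phenomic prediction (TPP) in replicated plant
    breeding trials phenotyped by repeated drone surveys. Computes vegetation
    indices and percentile canopy heights from band stacks and plot polygons,
    decomposes temporal plot phenotypes with a flight-nested random-effects
    model (EM-REML or balanced ANOVA), derives growth-curve and area-under-curve
    features, and predicts end-of-season agronomic traits with penalized
    regressions, random forests and GBLUP genomic prediction under four
    cross-validation schemes sharing one split plan. Includes a synthetic-trial
    generator with known truth for validation, down to renderable plot rasters.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    Matrix,
    glmnet,
    ranger,
    minpack.lm,
    pracma,
    jsonlite,
    yaml,
    tiff
Suggests:
    testthat (>= 3.0.0),
    lme4,
    withr,
    optparse
Config/testthat/edition: 3
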