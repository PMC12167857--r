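Package: sdmflow
Title: Ensemble Species Distribution Modelling Pipelines with Virtual-Species Validation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-native toolkit for ensemble species distribution
    modelling (SDM) of invasion and establishment risk. Provides occurrence
    cleaning, grid rarefaction and spatial thinning, surface-range-envelope
    pseudo-absence sampling within a dispersal buffer, iterative
    correlation/VIF predictor selection, a six-algorithm suitability model
    battery (GLM, boosted trees, random forest, classification trees,
    maxent-style elastic net, extreme gradient boosting) evaluated by TSS and
    ROC AUC on repeated 70:30 splits, TSS-weighted ensemble prediction with
    permutation variable importance, coefficient-of-variation uncertainty
    maps, max-TSS binarization, and expansion/contraction range-shift
    accounting between climate scenarios. A virtual-species simulator with
    known logistic niches makes the whole pipeline testable end to end
    without external data downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    geosphere,
    ggplot2,
    glmnet,
    jsonlite,
    purrr,
    randomForest,
    rlang,
    rpart,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    xgboost,
    yaml
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
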