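Package: enmplan
Title: Maximum-Entropy Niche Modelling and Priority-Area Planning
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale pipeline for maximum-entropy species distribution
    modelling and systematic conservation planning. Provides occurrence
    thinning and collinearity-based variable selection, an L1-regularized
    maximum-entropy suitability model with linear, quadratic, product,
    threshold and hinge features, candidate-model calibration by partial
    ROC, omission rate and AICc, two-threshold habitat classification with
    zonal area accounting, climate-scenario range-change and centroid
    migration analysis, and a simulated-annealing minimum-set planner with
    boundary-length and species-penalty controls. Includes a synthetic-data
    generator with known ground truth so every stage is testable without
    external downloads, plus readers and writers for ESRI ASCII grids,
    single-band GeoTIFF, occurrence CSV, and Marxan-style planning files.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    geosphere,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
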