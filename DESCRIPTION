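Package: allomap
Title: Sensitivity of Lidar Biomass Maps to Allometric Model Selection
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for quantifying how the choice of allometric model family
    (Jenkins-type generalized ln-ln equations, Chojnacky-type regroupings, or
    the US Forest Service Component Ratio Method) propagates into plot-level
    and county-level aboveground forest biomass estimates. Provides per-tree
    biomass engines backed by a delimited-text coefficient registry,
    height imputation with a lidar-pixel cap, Bitterlich variable-radius plot
    expansion to per-hectare density, a canopy height/cover/intensity lidar
    metric suite, outlier filtering, random-forest biomass modeling with
    out-of-bag diagnostics, model-assisted survey estimation of county means
    and standard errors, between-family comparison statistics, and a
    synthetic forest inventory + lidar generator so every stage is testable
    without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    randomForest,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
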