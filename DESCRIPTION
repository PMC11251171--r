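Package: mycoforest
Title: Mycorrhizal Tree Dominance and Forest Carbon Stock Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Plot-level computation and statistical inference linking
    ectomycorrhizal (EcM) tree dominance to tree, soil, and whole-forest
    carbon stocks in temperate forest inventories. Provides basal-area
    mycorrhizal dominance metrics, allometric tree carbon and layered soil
    organic carbon density, Rao's quadratic entropy functional diversity,
    a compositional (importance value x climax adaptation value) succession
    index, seasonality-based climate scoring, linear mixed-effects inference
    with ecoregion random intercepts and moderation analysis, ecoregion-
    stratified subsampling bootstraps, random-forest driver screening,
    from-scratch piecewise structural equation modelling with d-separation
    tests and Fisher's C, fungal guild community summaries, and a synthetic
    forest-inventory generator with known ground truth for end-to-end
    validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    lme4,
    lmerTest,
    randomForest,
    cluster,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    car,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
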