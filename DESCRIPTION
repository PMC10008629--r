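Package: arcbiodiv
Title: Ensemble Species Distribution Modelling and Biodiversity Change
    Analysis for Arctic Seas
Version: 0.1.0
Authors@R:
    person("Pan-Arctic Biodiversity", "Pipeline Maintainers",
           email = "maintainers@example.org", role = c("aut", "cre"))
Description: A reproducible pipeline for pan-Arctic marine biodiversity
    analysis on gridded annual-summer environmental data: virtual-species
    simulation with warming and sea-ice decline, occurrence cleaning and
    distance-based spatial thinning, two-round pseudo-absence sampling with
    environmental profiling, multi-algorithm ensemble species distribution
    models with committee-mean averaging gated on the True Skill Statistic,
    species-richness trend and accrual mapping, Sorensen beta-diversity
    partitioned into turnover and nestedness, probabilistic (hypergeometric)
    pairwise species co-occurrence classification, and pixel-wise
    Mann-Kendall climate/productivity hotspot detection.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    glmnet,
    mgcv,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
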