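Package: beflitter
Title: Diversity Effects on Leaf-Litter Decomposition in Microcosm Experiments
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Analysis of biodiversity-ecosystem functioning (BEF) litter
    experiments in aquatic microcosms. Computes leaching-corrected litter
    mass loss, fine particulate organic matter (FPOM) production and
    detritivore growth from raw microcosm tables; partitions net diversity
    effects on decomposition into complementarity and selection effects by
    additive partitioning; derives trait-variability metrics (standardized
    Euclidean trait distances, mass-weighted mixture trait means); fits
    heteroscedastic one-way models with Tukey-Kramer pairwise comparisons
    and trait-effect regressions; and generates seeded synthetic
    experiments with injectable complementarity and selection mechanisms
    so the whole pipeline can be verified by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    nlme,
    multcomp,
    readxl
Config/testthat/edition: 3
RoxygenNote: 7.3.3
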