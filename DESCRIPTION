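Package: nichepart
Title: Trophic Niche Partitioning Analysis for Lake Fish Communities
Version: 0.1.0
Authors@R:
    person("Fyresvatn", "Analytics", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for quantifying trophic niche partitioning in a
    three-species salmonid lake community from gill-net survey data,
    stomach contents and stable isotopes. Implements catch-per-unit-effort
    (CPUE) habitat-use metrics, volumetric stomach-content diet composition
    (percent prey abundance), Schoener's overlap index for diet and habitat,
    PERMANOVA on Bray-Curtis dissimilarity matrices with reduced-model
    residual permutation, a Bayesian stable-isotope mixing model with
    trophic-enrichment correction and concentration dependence, and
    isotopic-niche geometry (standard ellipse areas SEA/SEAc, convex-hull
    total area, and pairwise ellipse overlap). A seeded synthetic-data
    generator reproduces the statistical structure of the survey design so
    that every analysis stage is testable without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    grDevices,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
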