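Package: seedmb
Title: Eco-Evolutionary Analysis of Seed Microbiome Communities
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for analysing host-associated (seed) bacterial and fungal
    OTU tables along a host evolutionary gradient: cumulative-sum-scaling and
    Hellinger normalization, alpha diversity and Lorenz/Gini abundance
    inequality, Bray-Curtis ordination (PCoA, distance-based RDA) with
    PERMANOVA and Mantel tests, phylosymbiosis testing via normalized
    Robinson-Foulds congruence against randomized-tree nulls, zero-inflated
    Gaussian differential-abundance testing with empirical-Bayes moderated t
    statistics and core-OTU calling, random-forest classification of host
    domestication status with cross-validated feature-elimination curves,
    compositionality-robust (SparCC) co-occurrence networks with hub
    detection, and pedigree-based vertical-transmission analysis. Includes a
    synthetic-community generator with known ground truth for validating
    every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    vegan,
    igraph,
    randomForest,
    MASS,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    pROC,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
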