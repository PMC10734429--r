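Package: forageome
Title: Foraging-Phenotype Gut-Microbiome Analytics for Longitudinally
    Sampled Wild Birds
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline linking host foraging phenotype (marine
    specialist, terrestrial specialist, or habitat switcher) to gut
    microbiome diversity, composition, stability and body-condition
    dynamics from 16S amplicon sequence variant (ASV) count tables.
    Implements taxon pruning and prevalence-based contaminant removal,
    rarefaction richness with group-balanced bootstrapping, centred
    log-ratio (CLR) ordination with permutational multivariate ANOVA
    and dispersion tests, bootstrap shared/unique-taxa partitioning with
    bipartite network export, permutational Jaccard t-tests, indicator
    value analysis, within-individual centroid-distance stability, and a
    profile-likelihood random-intercept linear mixed model engine with
    AICc dredging for body-condition trajectories. A synthetic-study
    generator reproduces the sampling design so every stage can be
    validated against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    igraph
Suggests:
    testthat (>= 3.0.0),
    withr,
    biomformat,
    vegan,
    lme4
Config/testthat/edition: 3
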