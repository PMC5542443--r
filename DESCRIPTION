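Package: finekin
Title: Fine-Scale Spatial Genetic Structure of Plant Populations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Within-population spatial population genetics for georeferenced
    diploid microsatellite genotypes and maternally inherited plastid
    haplotypes. Implements Loiselle kinship correlograms with permutation
    tests and the Sp statistic, spatially weighted principal component
    analysis with global (G) and local (L) Monte-Carlo tests, a
    STRUCTURE-style Bayesian admixture Gibbs sampler with L(K) and Delta-K
    model selection, per-population diversity, inbreeding, null-allele and
    clonality statistics, and a battery of cyto-nuclear and habitat
    association tests (Weir-Cockerham F_ST, ANOVA on sPCA scores, Fisher,
    partial Mantel, pooled t and exact Spearman tests). A forward-in-time
    spatially explicit simulator generates synthetic datasets with the
    drift-dispersal structure the analyses assume, so every stage is
    testable without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    yaml,
    jsonlite,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    vegan,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
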