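Package: paleoterrapin
Title: Integrated Demographic History and Paleoclimate Niche Analysis for
    Terrapin and Tortoise Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers effective population size (Ne) trajectories from single
    diploid genomes with a pairwise sequentially Markovian coalescent hidden
    Markov model, reconstructs suitable habitat area through paleoclimate
    periods with a Maxent-style presence-background niche model, and links
    the two with trend-coding association statistics (chi-squared, Phi),
    phylogenetic generalized least squares of heterozygosity and mean Ne on
    conservation status and habitat area, and a position-representation-ratio
    statistic for assigning scaffolds to micro-dissected chromosomes. A
    synthetic-data module simulates coalescent genomes with known piecewise
    Ne, climate rasters with known suitability gradients, Brownian traits on
    known trees, and chromosome read tables, so every stage is testable
    offline.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    grDevices,
    ape,
    glmnet,
    geosphere,
    jsonlite,
    ggplot2
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    nlme,
    vcfR
Config/testthat/edition: 3
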