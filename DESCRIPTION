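Package: mesokin
Title: Parentage, Breeder and Mating Analysis for Mesocosm Translocation Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for closed-system mesocosm interbreeding
    experiments with microsatellite genotypes, motivated by translocation of
    cleaner fish (corkwing wrasse) between genetically divergent coastal
    populations. Provides GenePop input/output, per-locus and multilocus
    diversity and differentiation statistics (Nei-Chesser heterozygosities,
    rarefied allelic richness, Weir-Cockerham F-statistics, Markov-chain
    Hardy-Weinberg and linkage-disequilibrium tests, null-allele frequency,
    false discovery rate control), marker power indices (polymorphic
    information content, exclusion probabilities, probability of identity),
    exclusion- and likelihood-based trio parentage assignment with hybrid
    classification, effective-number-of-breeders estimation from family-size
    variance, logistic and Poisson models of mating success, and a fully
    seeded synthetic mesocosm simulator with known pedigree truth for
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
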