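Package: ldnascan
Title: Linkage-Disequilibrium Network Scans for Parallel Marine-Freshwater Selection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Comparative outlier analysis of genotype likelihoods for detecting
    genomic regions under parallel marine-freshwater selection. Implements nested
    linkage-disequilibrium network clustering (LDna-1/2/3) with synthetic
    multi-locus allele (SMLA) summaries, EMMAX-style mixed-model association of
    SMLAs with ecotype under four inflation/multiplicity correction regimes,
    consistency scoring of outlier regions over a parameter grid, excess absolute
    divergence (delta d_XY) diagnosis of ancient versus young haplotypes, and a
    population-genetic support layer (heterozygosity, nucleotide diversity,
    Watterson's theta, Weir-Cockerham F_ST with block bootstrap, and
    isolation-by-distance regression under the maximum-likelihood population
    effects correlation structure). Includes a metapopulation simulator that
    generates beagle-format genotype likelihoods with planted parallel haplotype
    blocks for method validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    geosphere
Suggests:
    testthat (>= 3.0.0),
    igraph,
    jsonlite
Config/testthat/edition: 3
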