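Package: bathypop
Title: Population Genetics of Deep-Sea Fish Across Oceanographic Barriers
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for the population-genetic analysis of two-basin marine
    species sampled for nuclear microsatellites and mitochondrial sequence
    data. Implements per-locus and per-population diversity statistics
    (observed and unbiased expected heterozygosity, rarefied allelic
    richness, haplotype and nucleotide diversity), Weir-Cockerham F
    statistics, Phi-ST from pairwise sequence differences, Jost's D,
    hierarchical AMOVA with grouping search, isolation-by-distance Mantel
    tests, frequency PCA, neutrality and demographic tests (Tajima's D,
    Fu's Fs, R2, heterozygosity-excess bottleneck tests), median-joining
    haplotype networks, a backward-time coalescent simulator of
    two-population divergence scenarios with stepwise-mutation
    microsatellites and K2P sequence evolution, approximate Bayesian
    computation for scenario choice and divergence-time estimation, and
    drift-based power analysis of sampling designs. A synthetic-data
    generator produces study-like six-locality datasets with controlled
    truth so the whole pipeline can be exercised without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    nnet,
    yaml,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    ape,
    vegan
Config/testthat/edition: 3
RoxygenNote: 7.3.3
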