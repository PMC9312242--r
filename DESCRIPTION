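Package: ssrpopgen
Title: Microsatellite Marker Development and Population Genetic Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for developing microsatellite (SSR) markers from genome
    sequence and analysing codominant diploid genotype data from wild
    populations. Detects perfect 2-5 bp tandem repeats in FASTA sequence and
    summarises canonical motif classes; screens candidate primer pairs against
    length, product-size and melting-temperature windows with exact-match
    in-silico PCR; reads and writes GenePop genotype tables; computes per-locus
    diversity statistics (Na, Ne, observed and Nei's unbiased expected
    heterozygosity, Botstein polymorphic information content, Monte-Carlo exact
    Hardy-Weinberg tests); partitions variance with a two-level AMOVA giving
    global and pairwise Fst with permutation p-values; builds UPGMA dendrograms
    from Nei's standard genetic distance; and fits a lightweight Gibbs-sampling
    admixture model with Evanno delta-K model selection. A synthetic-data
    module generates planted-SSR genomes and Balding-Nichols multi-population
    genotype datasets with known truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    Biostrings,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
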