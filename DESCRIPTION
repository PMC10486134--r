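Package: flavicomp
Title: Comparative Genomics of Insect-Specific Flaviviruses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-native toolkit for reference-anchored comparative
    genomics of insect-specific flavivirus isolates. Provides banded global
    pairwise alignment of ~11 kb genomes, single-nucleotide variant calling
    with codon-aware synonymous/nonsynonymous classification over a
    mature-peptide genome partition, per-region and sliding-window similarity
    profiling, substitution-spectrum summaries, TN93/neighbor-joining
    phylogenetics with bootstrap support, detection of -1 programmed
    ribosomal frameshift slippery heptamers with downstream stem-loop
    verification, pooled mosquito surveillance arithmetic, and a synthetic
    genome generator with fully known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
LinkingTo:
    Rcpp
Suggests:
    phangorn,
    testthat (>= 3.0.0),
    vcfR,
    withr
Config/testthat/edition: 3
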