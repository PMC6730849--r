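Package: matloci
Title: Detection and Characterization of Fused Fungal Mating-Type Loci
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Comparative-genomic toolkit for fused fungal mating-type (MAT)
    loci of the kind found across the Trichosporonales: consensus-motif
    scanning for lipopeptide pheromone precursor genes, reciprocal-best-hit
    assignment of MAT gene roles against a reference panel, detection and
    allele classification (A1/A2/A1*/A2*) of physically linked HD and P/R
    loci, ortholog-anchor synteny and inversion-breakpoint analysis,
    Nei-Gojobori (1986) synonymous divergence with Jukes-Cantor correction
    and bootstrap standard errors, sliding-window GC and BLAST-like
    similarity tracks, relative synonymous codon usage, and neighbor-joining
    gene genealogies classified for trans-species polymorphism. Includes a
    synthetic-genome simulator that plants fused MAT regions with inversions,
    deep pheromone-receptor allele divergence, mating-type-specific
    divergence and AT-biased composition, together with a complete truth
    record for parameter-recovery validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    Rcpp,
    Biostrings,
    dplyr,
    generics,
    GenomicRanges,
    ggplot2,
    purrr,
    rlang,
    rtracklayer,
    S4Vectors,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
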