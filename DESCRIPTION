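Package: pancore
Title: Bacterial Pangenome Analysis with Bidirectional-Best-Hit Orthology
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Comparative-genomics toolkit for genus-level bacterial genome
    sets: ortholog assignment by bidirectional best hits over exact
    Smith-Waterman protein alignment, partition of gene families into core,
    accessory and singleton classes, pan- and core-genome development curves
    by genome subsampling, Heaps'-law and exponential-decay curve fitting,
    fragment-based average nucleotide identity (ANI) and ortholog-based
    average amino-acid identity (AAI) matrices with genus/species rank
    classification, and a seeded synthetic genome-set generator with known
    ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    ggplot2,
    generics,
    igraph,
    jsonlite,
    minpack.lm,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    rtracklayer,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
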