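Package: ltrcisnet
Title: Structural Detection of LTR Retrotransposons and Signed Cis-Regulatory
    Networks with Neighboring Genes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detects LTR retrotransposons in a genome by paired direct-repeat
    search with identity, separation and target-site-duplication criteria;
    classifies elements against gene exons (In/Part/Stream); identifies
    cis-target genes within a configurable window of independent elements;
    quantifies expression by FPKM, applies a replicate-consistency filter and
    a negative-binomial exact test to call differentially expressed elements
    and genes; joins them into a signed element-gene interaction network; and
    scans envelope-like open reading frames for furin-cleavage and
    fusion-peptide motifs. A synthetic-data generator plants elements, gene
    models and count matrices with known truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    stringr,
    readr,
    ggplot2,
    generics,
    jsonlite,
    stats,
    utils,
    Biostrings,
    rtracklayer,
    GenomicRanges,
    IRanges,
    S4Vectors
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    edgeR,
    optparse,
    withr,
    yaml
Config/testthat/edition: 3
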