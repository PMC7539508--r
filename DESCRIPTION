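Package: selenoscan
Title: Selenoprotein Gene Discovery and Comparative Selenoproteomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Discovery of selenoprotein genes in genomic and transcript
    sequence: enumeration of open reading frames that read through in-frame
    TGA codons as selenocysteine (Sec, U), Sec-aware local alignment against
    a reference selenoprotein family database, grammar-based detection of
    SECIS stem-loop elements in 3'-UTRs, frameshift-aware pseudogene calling
    with EST support, and fusion-gene detection. Comparative analytics build
    gene clusters, flanking-duplication events, and the species-by-family
    presence matrix with hierarchical clustering. A synthetic-cohort
    generator plants genes of every class with a machine-readable truth
    table for end-to-end evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    dplyr,
    tidyr,
    purrr,
    tibble,
    stringr,
    rlang,
    ggplot2,
    jsonlite,
    generics,
    stats,
    utils,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    vegan
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
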