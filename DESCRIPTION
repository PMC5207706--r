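Package: srnapeaks
Title: Discovery of Promoter- and Terminus-Associated Small RNA Peaks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Transcriptome-wide discovery of promoter-associated (PASR) and
    terminus-associated (TASR) small RNAs on protein-coding genes. Extracts
    strand-aware boundary regions around transcription start sites and
    termini from a genome and GFF3 annotation, maps collapsed small-RNA
    libraries into them by perfect matching, normalizes to reads per
    million, and calls peaks with a 50-nt scrolling-window density
    criterion. Downstream classifiers annotate each peak with Argonaute
    (AGO1/AGO4) loading preference, organ-specific accumulation,
    DCL/RDR/Pol IV biogenesis dependence, dsRNA-seq coverage and DNA
    methylation overlap. A self-contained simulator generates genomes,
    annotations and the full library ensemble with planted ground truth
    for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    rlang,
    ggplot2,
    generics,
    withr,
    Biostrings,
    GenomicRanges,
    IRanges,
    rtracklayer,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
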