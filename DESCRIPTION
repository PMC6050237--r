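Package: evcargo
Title: Profiling the Small RNA and Protein Cargo of Extracellular Vesicles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for characterising the small RNA transcriptome and the
    proteome of extracellular vesicles (EVs) and their parental cells. The
    package implements a three-tier priority annotation cascade for 17-35 nt
    aligned reads ('small RNA' before 'rRNA' before 'other RNA'), including
    reciprocal-overlap deduplication of rRNA annotation sources, tRNA
    isoacceptor pooling and count-threshold normalisation; descriptive
    composition statistics (category and biotype fractions, read-length
    histograms, 5'-base composition, mature-piRNA criteria, top-N cumulative
    coverage, correlation and hierarchical clustering on one-minus-Pearson
    distances); a matched proteome workflow based on MS-Area abundance shares,
    rank-cumulative coverage, set-overlap fractions and a hypergeometric
    GO-term overrepresentation test with Benjamini-Hochberg adjustment; and a
    synthetic-data generator that emits annotation files, aligned reads and
    protein tables with known ground truth so every stage of the pipeline is
    testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    readr,
    stringr,
    rlang,
    ggplot2,
    generics,
    withr,
    GenomicRanges,
    IRanges,
    BiocGenerics,
    GenomeInfoDb,
    S4Vectors,
    GenomicAlignments,
    Biostrings,
    Rsamtools,
    rtracklayer,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
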