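Package: riboclast
Title: Ribosome Profiling Analysis of Endonucleolytic mRNA Cleavage and
    Alternative ORF Translation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing ribosome profiling and RNA-seq data from
    cells undergoing widespread endonucleolytic mRNA cleavage (for example
    by activated RNase L or electroporated RNase A). Provides P-site
    assignment and offset calibration for footprint alignments in
    transcript coordinates, region-resolved counting (5'UTR, CDS, 3'UTR,
    uORF), UTR:ORF occupancy ratios and metagene profiles that quantify
    alternative-ORF translation on cleavage fragments, a simplified
    differential-expression stage with gene-set summaries, translation
    efficiency computation and classification, and detection of upstream
    ORF translation shifts during the integrated stress response. A
    synthetic-data generator simulates motif-specific fragmentation,
    global mRNA loss with transcriptional compensation, uORF initiation
    shifts and ribosome re-initiation on 3' fragments, with full ground
    truth for recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    graphics,
    data.table,
    jsonlite,
    yaml,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    Biostrings,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    withr,
    Rsamtools,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
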