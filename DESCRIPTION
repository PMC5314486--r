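Package: epicross
Title: Integrative Two-Condition Analysis of Histone-Mark Crosstalk
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An integrative ChIP-seq/RNA-seq pipeline for comparing two-condition
    epigenomes, centred on the crosstalk between gene-body H2B monoubiquitination
    (H2Bub1) and promoter H3K4me3 domain geometry. Provides coverage and
    annotation I/O, a local-Poisson peak caller, peak width/height/summit
    statistics with broad/sharp/random H3K4me3 domain classification and
    strand-aware summit-shift estimation, H2Bub1 occupancy quartile
    stratification of expression responses, windowed differential histone
    occupancy with Benjamini-Hochberg control, combinatorial active-enhancer
    calling, basal-plus-extension regulatory-domain gene association,
    position-weight-matrix motif scanning with Fisher and Z enrichment scores,
    and a synthetic two-condition epigenome generator with a ground-truth table
    so every stage is verifiable by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    yaml,
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    DESeq2
Config/testthat/edition: 3
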