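Package: ncMeth
Title: Aberrant Promoter Methylation Patterns of Non-Coding RNAs from
    Bin-Level Methylome Counts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Calls differentially methylated regions (DMRs) between a
    tumor and a control cohort from fixed-width (100-bp) bin read-count
    tracks such as those produced by MBDCap-seq, maps them onto the
    +/-2-kb promoters of long non-coding RNAs, pri-miRNAs and
    protein-coding genes, and classifies each aberrantly methylated
    promoter into one of five CpG-island-context patterns (confined to
    the CGI, 5' shore, 3' shore, partial CGI overlap, or CGI-lacking).
    Downstream modules integrate promoter methylation with expression
    to nominate silencing and activating candidates, score Z-score
    biomarker panels by ROC analysis, and quantify functional
    similarity between pattern groups. A synthetic-data generator with
    a ground-truth manifest supports end-to-end recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
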