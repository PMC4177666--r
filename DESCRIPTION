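Package: polygate
Title: Joint Chromatin and Expression Gating of Polycomb Target Genes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An integrative ChIP-seq/RNA-seq pipeline for classifying
    transcripts by Polycomb-associated histone marks and transcriptional
    response. Quantifies H3K27me3 and H3K27me3S28p signal in windows around
    transcription start sites with library-size and region-size
    normalization, calls transcripts positive or negative for a mark by
    fitting a normal distribution to the genome-wide signal and
    auto-thresholding at a chosen expected-by-chance rate, runs a minimal
    negative-binomial differential-expression stage (median-of-ratios size
    factors, method-of-moments dispersion, Wald test, Benjamini-Hochberg
    correction), and gates transcripts into joint chromatin-expression
    subpopulations, with acute-versus-chronic comparison, induced-fraction
    statistics, and hypergeometric term enrichment. Includes a
    synthetic-data generator with planted truth so every stage can be
    validated end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    stats,
    tools,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    withr,
    DESeq2,
    jsonlite
Config/testthat/edition: 3
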