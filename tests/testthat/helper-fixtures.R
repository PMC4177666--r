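# Small constructors shared across test files.

suppressPackageStartupMessages(library(GenomicRanges))

gr_reads <- function(starts, width = 36L, chrom = "chr1", strand = "+") {
  GenomicRanges::GRanges(chrom,
                         IRanges::IRanges(start = starts, width = width),
                         strand = strand)
}

gr_windows <- function(starts, ends, ids = sprintf("tx%d", seq_along(starts)),
                       chrom = "chr1", strand = "+") {
  GenomicRanges::GRanges(chrom, IRanges::IRanges(start = starts, end = ends),
                         strand = strand, transcript_id = ids)
}

# Brute-force per-read / per-window overlap counter (independent oracle for
# the countOverlaps-based quantitation path).
brute_overlap_counts <- function(reads, windows) {
  rs <- GenomicRanges::start(reads); re <- GenomicRanges::end(reads)
  rc <- as.character(GenomicRanges::seqnames(reads))
  vapply(seq_along(windows), function(i) {
    ws <- GenomicRanges::start(windows)[i]; we <- GenomicRanges::end(windows)[i]
    wc <- as.character(GenomicRanges::seqnames(windows))[i]
    n <- 0L
    for (j in seq_along(reads)) {
      if (rc[j] == wc && rs[j] <= we && re[j] >= ws) n <- n + 1L
    }
    n
  }, 0L)
}

# Brute-force BH step-up (independent oracle for bh_adjust).
brute_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

# Exact hypergeometric upper tail by combinatorial summation (oracle for
# the phyper-based enrichment p-value); background sizes <= ~200.
brute_hyper_upper <- function(hits, term_size, background_size, subset_size) {
  ks <- hits:min(term_size, subset_size)
  sum(choose(term_size, ks) *
        choose(background_size - term_size, subset_size - ks)) /
    choose(background_size, subset_size)
}

write_bed6 <- function(gr, path) {
  df <- data.frame(as.character(GenomicRanges::seqnames(gr)),
                   GenomicRanges::start(gr) - 1L,
                   GenomicRanges::end(gr),
                   if (!is.null(gr$transcript_id)) gr$transcript_id else ".",
                   0L,
                   as.character(GenomicRanges::strand(gr)))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
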