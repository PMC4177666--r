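#' Quantify ChIP-seq signal in TSS windows
#'
#' Counts reads in each transcript's TSS window and normalizes the count to
#' library size and window size:
#' `normalized = raw_count * (1e7 / library_size) * (1000 / window_width)`,
#' i.e. reads per 1 kbp per 10 million reads. Every window gets a record;
#' windows with no overlapping reads score 0.
#'
#' Two counting modes are supported: `"overlap"` counts every read
#' overlapping the window by at least 1 bp (default), `"fivep"` counts a
#' read only if its 5' end falls inside the window.
#'
#' @param reads `GRanges` of aligned reads.
#' @param windows `GRanges` of TSS windows with a `transcript_id` column
#'   (from [tss_windows()]).
#' @param library_size Total mapped reads in the track (> 0); defaults to
#'   `length(reads)`.
#' @param mode Counting rule, `"overlap"` or `"fivep"`.
#' @return data.frame with columns `transcript_id`, `raw_count`,
#'   `normalized`, `window_width`.
#' @examples
#' w <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1001, 3000),
#'                             strand = "+", transcript_id = "tx1")
#' r <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1500 + 0:3, width = 36))
#' quantify_tss_signal(r, w, library_size = 2e6)  # 4 * 5 * 0.5 = 10
#' @export
quantify_tss_signal <- function(reads, windows,
                                library_size = length(reads),
                                mode = c("overlap", "fivep")) {
  mode <- match.arg(mode)
  stopifnot(is(reads, "GRanges"), is(windows, "GRanges"))
  if (is.null(windows$transcript_id))
    stop("windows must carry a transcript_id column", call. = FALSE)
  if (!is.numeric(library_size) || length(library_size) != 1L || library_size <= 0)
    stop("library_size must be a positive count", call. = FALSE)
  qreads <- if (mode == "fivep") {
    GenomicRanges::resize(reads, width = 1L, fix = "start")
  } else reads
  raw <- GenomicRanges::countOverlaps(windows, qreads, ignore.strand = TRUE)
  ww <- width(windows)
  data.frame(transcript_id = windows$transcript_id,
             raw_count = raw,
             normalized = raw * (1e7 / library_size) * (1000 / ww),
             window_width = ww,
             stringsAsFactors = FALSE)
}

#' Normalize mark signal to total histone H3
#'
#' Per-transcript ratio of a mark's normalized signal to the normalized
#' signal of a general-H3 track quantified over the same windows, used to
#' correct apparent mark levels for local nucleosome density. Transcripts
#' with zero H3 signal have an undefined ratio: they get `NA` and are
#' flagged so downstream gating can exclude them on this axis.
#'
#' @param mark_quant,h3_quant data.frames from [quantify_tss_signal()] over
#'   the same transcripts (same order).
#' @return data.frame with columns `transcript_id`, `ratio`, `undefined`.
#' @export
h3_normalize <- function(mark_quant, h3_quant) {
  if (!identical(mark_quant$transcript_id, h3_quant$transcript_id))
    stop("mark and H3 quantifications index different transcripts", call. = FALSE)
  undef <- h3_quant$normalized == 0
  ratio <- ifelse(undef, NA_real_, mark_quant$normalized / h3_quant$normalized)
  data.frame(transcript_id = mark_quant$transcript_id,
             ratio = ratio, undefined = undef, stringsAsFactors = FALSE)
}
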