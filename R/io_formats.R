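#' Read a transcript annotation from BED or GTF
#'
#' Parses a transcript annotation into a `GRanges` with `transcript_id` and
#' `gene_id` metadata columns. All coordinates follow the usual Bioconductor
#' convention (1-based, closed intervals); BED input (0-based half-open) and
#' GTF input (1-based closed) are both converted on read, so a GTF feature
#' spanning 100-200 and a BED line spanning 99-200 describe the same locus.
#'
#' For BED input the `name` field becomes `transcript_id`. BED carries no
#' separate gene identifier, so `gene_id` is set equal to `transcript_id`
#' (one transcript per gene); GTF input uses the `transcript_id` and
#' `gene_id` attributes of its `transcript` features.
#'
#' @param path Path to the annotation file.
#' @param format `"bed"` or `"gtf"`. Defaults to guessing from the file
#'   extension.
#' @return A `GRanges`, one range per transcript, with metadata columns
#'   `transcript_id` and `gene_id`. Strand is `+` or `-` for every record.
#' @examples
#' bed <- tempfile(fileext = ".bed")
#' writeLines(c("chr1\t100\t200\ttxA\t0\t+", "chr1\t300\t400\ttxB\t0\t-"), bed)
#' read_transcript_annotation(bed)
#' @export
read_transcript_annotation <- function(path, format = c("auto", "bed", "gtf")) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, bed = "bed", gtf = "gtf", gff = "gtf",
                     stop("cannot guess annotation format from extension '", ext,
                          "'; pass format explicitly", call. = FALSE))
  }
  if (!file.exists(path)) stop("annotation file not found: ", path, call. = FALSE)

  if (format == "bed") {
    gr <- .read_bed_validated(path, min_fields = 6L)
    if (length(gr) == 0L) return(.empty_annotation())
    mcols(gr) <- S4Vectors::DataFrame(transcript_id = gr$name, gene_id = gr$name)
  } else {
    gr <- rtracklayer::import(path, format = "gtf")
    gr <- gr[!is.na(gr$type) & gr$type == "transcript"]
    if (length(gr) == 0L) return(.empty_annotation())
    if (is.null(gr$transcript_id) || anyNA(gr$transcript_id))
      stop("GTF transcript feature lacks a transcript_id attribute", call. = FALSE)
    gid <- if (is.null(gr$gene_id)) gr$transcript_id else gr$gene_id
    mcols(gr) <- S4Vectors::DataFrame(transcript_id = gr$transcript_id, gene_id = gid)
  }
  bad_strand <- !(as.character(strand(gr)) %in% c("+", "-"))
  if (any(bad_strand))
    stop("annotation records without a +/- strand: ",
         paste(utils::head(gr$transcript_id[bad_strand], 5L), collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(gr$transcript_id))
    stop("duplicated transcript_id in annotation: ",
         paste(utils::head(unique(gr$transcript_id[duplicated(gr$transcript_id)]), 5L),
               collapse = ", "), call. = FALSE)
  gr
}

.empty_annotation <- function() {
  gr <- GenomicRanges::GRanges()
  mcols(gr) <- S4Vectors::DataFrame(transcript_id = character(0), gene_id = character(0))
  gr
}

# Pre-validate a BED file line by line so parse errors carry a line number,
# then hand the file to rtracklayer for the actual import.
.read_bed_validated <- function(path, min_fields = 6L) {
  lines <- readLines(path)
  keep <- !grepl("^(#|track|browser)", lines) & nzchar(trimws(lines))
  body <- lines[keep]
  lineno <- which(keep)
  if (length(body) == 0L) return(GenomicRanges::GRanges(name = character(0)))
  fields <- strsplit(body, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < min_fields))
    stop("malformed BED line ", lineno[which(nf < min_fields)[1L]],
         ": expected >= ", min_fields, " tab-separated fields", call. = FALSE)
  starts <- suppressWarnings(as.numeric(vapply(fields, `[`, "", 2L)))
  ends   <- suppressWarnings(as.numeric(vapply(fields, `[`, "", 3L)))
  bad <- is.na(starts) | is.na(ends) | starts < 0 | starts >= ends
  if (any(bad))
    stop("malformed BED line ", lineno[which(bad)[1L]],
         ": start/end must satisfy 0 <= start < end", call. = FALSE)
  if (min_fields >= 6L) {
    strands <- vapply(fields, `[`, "", 6L)
    badstr <- !(strands %in% c("+", "-"))
    if (any(badstr))
      stop("malformed BED line ", lineno[which(badstr)[1L]],
           ": unknown strand symbol '", strands[which(badstr)[1L]], "'",
           call. = FALSE)
  }
  rtracklayer::import(path, format = "bed")
}

#' Transcription start site windows
#'
#' Builds the window of `flank` bp on each side of every transcript's TSS:
#' the start of the range for `+` strand transcripts, the end for `-`
#' strand ones. Windows are clamped at position 1 (and at the chromosome end
#' when `seqlengths` are set), so windows near a chromosome edge may be
#' shorter than `2 * flank`.
#'
#' @param transcripts `GRanges` of transcripts (strand must be `+`/`-`).
#' @param flank Flank size in bp on each side of the TSS (default 1000,
#'   giving the 2-kb window used for promoter-proximal mark quantitation).
#' @return `GRanges` of windows, parallel to `transcripts`, metadata
#'   columns carried over.
#' @export
tss_windows <- function(transcripts, flank = 1000L) {
  stopifnot(is(transcripts, "GRanges"))
  flank <- as.integer(flank)
  if (is.na(flank) || flank <= 0L) stop("flank must be a positive integer", call. = FALSE)
  if (any(!as.character(strand(transcripts)) %in% c("+", "-")))
    stop("all transcripts must be stranded (+/-)", call. = FALSE)
  w <- suppressWarnings(GenomicRanges::promoters(transcripts,
                                                 upstream = flank,
                                                 downstream = flank))
  # clamp at the chromosome start; trim() additionally clamps at seqlengths
  start(w) <- pmax(start(w), 1L)
  suppressWarnings(GenomicRanges::trim(w))
}

#' Read aligned ChIP-seq reads from BED6 or minimal SAM
#'
#' Accepts either BED6 (one interval per uniquely mapped read) or a minimal
#' SAM text file. For SAM, unmapped (flag 0x4) and secondary (flag 0x100)
#' records are skipped and the number skipped is reported with a message;
#' reference widths are computed from the CIGAR string (M/D/N/=/X consume
#' reference).
#'
#' @param path Path to a `.bed` or `.sam` file.
#' @param format `"bed"`, `"sam"`, or `"auto"` (guess from extension).
#' @return `GRanges` of reads, one range per retained alignment, with the
#'   number of skipped records in `metadata()$skipped`.
#' @export
read_alignments <- function(path, format = c("auto", "bed", "sam")) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, bed = "bed", sam = "sam",
                     stop("cannot guess read format from extension '", ext, "'",
                          call. = FALSE))
  }
  if (!file.exists(path)) stop("read file not found: ", path, call. = FALSE)
  if (format == "bed") {
    gr <- .read_bed_validated(path, min_fields = 6L)
    mcols(gr) <- NULL
    S4Vectors::metadata(gr)$skipped <- 0L
    return(gr)
  }
  .read_minimal_sam(path)
}

# Minimal SAM text reader: mapped primary records only. R's alignment readers
# operate on BAM; plain-text SAM at this level is a fixed 11-column table.
.read_minimal_sam <- function(path) {
  lines <- readLines(path)
  body <- lines[!grepl("^@", lines) & nzchar(lines)]
  if (length(body) == 0L) {
    gr <- GenomicRanges::GRanges()
    S4Vectors::metadata(gr)$skipped <- 0L
    return(gr)
  }
  fields <- strsplit(body, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 11L)) {
    lineno <- which(!grepl("^@", lines) & nzchar(lines))[which(nf < 11L)[1L]]
    stop("malformed SAM line ", lineno, ": expected >= 11 fields", call. = FALSE)
  }
  flagv <- as.integer(vapply(fields, `[`, "", 2L))
  rname <- vapply(fields, `[`, "", 3L)
  pos <- as.integer(vapply(fields, `[`, "", 4L))
  cigar <- vapply(fields, `[`, "", 6L)
  if (anyNA(flagv) || anyNA(pos)) {
    lineno <- which(!grepl("^@", lines) & nzchar(lines))[which(is.na(flagv) | is.na(pos))[1L]]
    stop("malformed SAM line ", lineno, ": non-numeric FLAG or POS", call. = FALSE)
  }
  skip <- bitwAnd(flagv, 4L) != 0L | bitwAnd(flagv, 256L) != 0L
  n_skip <- sum(skip)
  if (n_skip > 0L)
    message("read_alignments: skipped ", n_skip, " unmapped/secondary SAM record(s)")
  keep <- !skip
  if (!any(keep)) {
    gr <- GenomicRanges::GRanges()
    S4Vectors::metadata(gr)$skipped <- n_skip
    return(gr)
  }
  widths <- vapply(cigar[keep], .cigar_ref_width, 0L, USE.NAMES = FALSE)
  str <- ifelse(bitwAnd(flagv[keep], 16L) != 0L, "-", "+")
  gr <- GenomicRanges::GRanges(rname[keep],
                               IRanges::IRanges(start = pos[keep], width = widths),
                               strand = str)
  S4Vectors::metadata(gr)$skipped <- n_skip
  gr
}

.cigar_ref_width <- function(cigar) {
  ops <- regmatches(cigar, gregexpr("[0-9]+[MIDNSHP=X]", cigar))[[1L]]
  if (length(ops) == 0L) stop("unparseable CIGAR: ", cigar, call. = FALSE)
  n <- as.integer(sub("[MIDNSHP=X]$", "", ops))
  op <- sub("^[0-9]+", "", ops)
  as.integer(sum(n[op %in% c("M", "D", "N", "=", "X")]))
}

#' Write a binned, library-normalized coverage track as bedGraph
#'
#' Bins each chromosome into fixed-width bins, counts reads overlapping each
#' bin (a read spanning two bins is counted in both), and scales counts to a
#' reference library of 10 million reads:
#' `value = count * 1e7 / library_size`. Output is bedGraph (0-based
#' half-open), a plain-text wiggle dialect, with a `track type=bedGraph`
#' header line; zero bins are omitted.
#'
#' @param reads `GRanges` of aligned reads.
#' @param bin_width Bin width in bp (> 0).
#' @param library_size Total reads in the library (> 0); typically
#'   `length(reads)`.
#' @param path Output file path.
#' @return (invisibly) a `GRanges` of the non-zero bins with a `score`
#'   column holding the normalized values.
#' @export
write_bedgraph <- function(reads, bin_width, library_size, path) {
  stopifnot(is(reads, "GRanges"))
  bin_width <- as.integer(bin_width)
  if (is.na(bin_width) || bin_width <= 0L) stop("bin_width must be > 0", call. = FALSE)
  if (!is.numeric(library_size) || length(library_size) != 1L || library_size <= 0)
    stop("library_size must be a positive count", call. = FALSE)

  if (length(reads) == 0L) {
    writeLines("track type=bedGraph", path)
    bins <- GenomicRanges::GRanges()
    bins$score <- numeric(0)
    return(invisible(bins))
  }
  chroms <- as.character(unique(seqnames(reads)))
  per_chrom <- lapply(chroms, function(ch) {
    r <- reads[seqnames(reads) == ch]
    lim <- max(end(r))
    n_bins <- ceiling(lim / bin_width)
    starts <- seq.int(1L, by = bin_width, length.out = n_bins)
    bins <- GenomicRanges::GRanges(ch, IRanges::IRanges(start = starts, width = bin_width))
    bins$score <- GenomicRanges::countOverlaps(bins, r) * 1e7 / library_size
    bins[bins$score > 0]
  })
  bins <- suppressWarnings(do.call(c, per_chrom))
  writeLines("track type=bedGraph", path)
  df <- data.frame(chrom = as.character(seqnames(bins)),
                   start = start(bins) - 1L,
                   end = end(bins),
                   value = bins$score)
  utils::write.table(df, path, append = TRUE, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(bins)
}
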