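#' Gate transcripts into joint chromatin-expression subpopulations
#'
#' Combines per-transcript H3K27me3 calls (made in the unlesioned
#' hemisphere, so the epitope is not masked by S28 phosphorylation),
#' H3K27me3S28p calls (made in the lesioned hemisphere), and
#' differential-expression results into chromatin strata and regulated
#' subpopulations:
#'
#' * stratum `double_positive`: K27me3+ and S28p+;
#' * stratum `k27_only`: K27me3+ but S28p-;
#' * every transcript additionally belongs to the `all` stratum.
#'
#' Regulated transcripts with `|log2fc| >= lfc_cut` receive a subpopulation
#' label: I (down) / II (up) in the double-positive stratum, III (down) /
#' IV (up) in the K27me3-only stratum, and V (down) / VI (up) for
#' regulated transcripts outside both K27me3+ strata. Note that
#' subpopulations V/VI are defined over *all* regulated transcripts; use
#' [subpopulation_counts()] for counts under that convention (a transcript
#' labelled II here also counts toward VI there).
#'
#' @param calls_k27 Mark calls for H3K27me3 (unlesioned), from
#'   [call_marks()].
#' @param calls_s28p Mark calls for H3K27me3S28p (lesioned).
#' @param de_results DE table from [run_de()].
#' @param lfc_cut Absolute log2 fold-change cutoff (default 0.58).
#' @return data.frame: `transcript_id`, `k27_positive`, `s28p_positive`,
#'   `stratum`, `regulated`, `log2fc`, `fold_class`, `subpopulation`.
#' @export
gate_subpopulations <- function(calls_k27, calls_s28p, de_results,
                                lfc_cut = 0.58) {
  ids <- de_results$transcript_id
  for (tab in list(calls_k27, calls_s28p)) {
    miss <- setdiff(ids, tab$transcript_id)
    if (length(miss) > 0L)
      stop("mark calls missing for transcripts: ",
           paste(head(miss, 5L), collapse = ", "),
           if (length(miss) > 5L) " ..." else "", call. = FALSE)
  }
  k27 <- calls_k27$positive[match(ids, calls_k27$transcript_id)]
  s28 <- calls_s28p$positive[match(ids, calls_s28p$transcript_id)]
  stratum <- ifelse(k27 & s28, "double_positive",
                    ifelse(k27, "k27_only", "unmarked"))
  lfc <- de_results$log2fc
  big <- abs(lfc) >= lfc_cut
  up <- lfc > 0
  sub <- rep("none", length(ids))
  lab <- de_results$regulated & big
  sub[lab & stratum == "double_positive"] <- ifelse(up[lab & stratum == "double_positive"], "II", "I")
  sub[lab & stratum == "k27_only"] <- ifelse(up[lab & stratum == "k27_only"], "IV", "III")
  sub[lab & stratum == "unmarked"] <- ifelse(up[lab & stratum == "unmarked"], "VI", "V")
  data.frame(transcript_id = ids, k27_positive = k27, s28p_positive = s28,
             stratum = stratum, regulated = de_results$regulated,
             log2fc = lfc, fold_class = de_results$fold_class,
             subpopulation = sub, stringsAsFactors = FALSE)
}

#' Subpopulation counts with genome-wide V/VI convention
#'
#' Counts transcripts per subpopulation. I-IV are read off the gate
#' labels; V and VI are counted over *all* regulated transcripts with a
#' fold change of at least `lfc_cut` down or up respectively, regardless
#' of chromatin stratum (so they include the transcripts in I-IV).
#'
#' @param gates data.frame from [gate_subpopulations()].
#' @param lfc_cut Absolute log2 fold-change cutoff (default 0.58).
#' @return Named integer vector with elements I-VI.
#' @export
subpopulation_counts <- function(gates, lfc_cut = 0.58) {
  big <- gates$regulated & abs(gates$log2fc) >= lfc_cut
  c(I = sum(gates$subpopulation == "I"),
    II = sum(gates$subpopulation == "II"),
    III = sum(gates$subpopulation == "III"),
    IV = sum(gates$subpopulation == "IV"),
    V = sum(big & gates$log2fc < 0),
    VI = sum(big & gates$log2fc > 0))
}

#' Percentage of changed transcripts that are induced
#'
#' `100 * up / (up + down)`, rounded half-up to the nearest integer
#' percent. With 339 up- and 52 down-regulated transcripts this gives 87.
#'
#' @param up_count,down_count Non-negative counts of >= 1.5-fold up- and
#'   down-regulated transcripts.
#' @return Integer percent; `NA` (with a warning) when both counts are 0.
#' @export
fraction_induced <- function(up_count, down_count) {
  stopifnot(up_count >= 0, down_count >= 0)
  if (up_count + down_count == 0) {
    warning("fraction_induced undefined: no changed transcripts", call. = FALSE)
    return(NA_integer_)
  }
  as.integer(floor(100 * up_count / (up_count + down_count) + 0.5))
}

#' Two-set Venn counts
#'
#' Exclusive and common element counts for two identifier sets (genes are
#' compared after collapsing transcripts to gene ids, so pass gene-level
#' sets).
#'
#' @param set_A,set_B Character vectors (duplicates ignored).
#' @return Named integer vector `(exclusive_A, common, exclusive_B)`.
#' @export
venn_counts <- function(set_A, set_B) {
  A <- unique(set_A); B <- unique(set_B)
  common <- length(intersect(A, B))
  c(exclusive_A = length(A) - common, common = common,
    exclusive_B = length(B) - common)
}

#' 2D histogram of fold change against chromatin signal
#'
#' Bins paired observations (typically log2 fold change on x and
#' normalized mark signal on y) on a rectangular grid. Bins are half-open
#' `[lo, hi)` except the last bin in each dimension, which is closed, so
#' every retained point lands in exactly one cell. Non-finite pairs are
#' dropped with a message.
#'
#' @param x,y Numeric vectors of equal length.
#' @param x_bins,y_bins Either a single bin count or a vector of
#'   monotonically increasing bin edges.
#' @return List with `counts` (matrix, rows = x bins, cols = y bins),
#'   `x_edges`, `y_edges`, `n_dropped`.
#' @export
histogram2d <- function(x, y, x_bins = 25L, y_bins = 25L) {
  if (length(x) != length(y)) stop("x and y must have equal length", call. = FALSE)
  keep <- is.finite(x) & is.finite(y)
  n_drop <- sum(!keep)
  if (n_drop > 0L) message("histogram2d: dropped ", n_drop, " non-finite point(s)")
  x <- x[keep]; y <- y[keep]
  edges <- function(v, bins) {
    if (length(bins) == 1L) {
      bins <- as.integer(bins)
      if (bins < 1L) stop("need at least one bin", call. = FALSE)
      r <- range(v)
      if (r[1] == r[2]) r <- r + c(-0.5, 0.5)
      seq(r[1], r[2], length.out = bins + 1L)
    } else {
      if (any(diff(bins) <= 0)) stop("bin edges must be strictly increasing", call. = FALSE)
      bins
    }
  }
  xe <- edges(x, x_bins); ye <- edges(y, y_bins)
  xi <- findInterval(x, xe, rightmost.closed = TRUE)
  yi <- findInterval(y, ye, rightmost.closed = TRUE)
  inside <- xi >= 1L & xi <= length(xe) - 1L & yi >= 1L & yi <= length(ye) - 1L
  counts <- matrix(0L, length(xe) - 1L, length(ye) - 1L)
  tab <- table(factor(xi[inside], levels = seq_len(nrow(counts))),
               factor(yi[inside], levels = seq_len(ncol(counts))))
  counts[] <- as.integer(tab)
  list(counts = counts, x_edges = xe, y_edges = ye,
       n_dropped = n_drop + sum(!inside))
}

#' Hypergeometric term enrichment
#'
#' For each annotation term, tests whether the term's genes are
#' over-represented in a gene subset relative to a background universe.
#' Fold enrichment is `(hits / subset_size) / (term_size / background_size)`
#' and the p-value is the hypergeometric upper tail `P[X >= hits]`;
#' p-values are BH-adjusted across the tested terms. Term sets are
#' intersected with the background first; terms with fewer than 2
#' background genes are skipped with a message.
#'
#' @param subset Character vector of genes, a subset of `background`.
#' @param term_map Named list: term id -> character vector of genes.
#' @param background Character vector, the gene universe.
#' @return data.frame: `term_id`, `hits`, `subset_size`, `term_size`,
#'   `background_size`, `fold_enrichment`, `pvalue`, `padj`, sorted by
#'   p-value.
#' @export
enrichment <- function(subset, term_map, background) {
  background <- unique(background)
  subset <- unique(subset)
  if (length(background) == 0L) stop("background is empty", call. = FALSE)
  if (!all(subset %in% background))
    stop("subset must be contained in the background", call. = FALSE)
  N <- length(background); k <- length(subset)
  rows <- lapply(names(term_map), function(tid) {
    term <- intersect(unique(term_map[[tid]]), background)
    m <- length(term)
    if (m < 2L) return(NULL)
    hits <- length(intersect(subset, term))
    fold <- (hits / k) / (m / N)
    p <- phyper(hits - 1L, m, N - m, k, lower.tail = FALSE)
    data.frame(term_id = tid, hits = hits, subset_size = k, term_size = m,
               background_size = N, fold_enrichment = fold, pvalue = p,
               stringsAsFactors = FALSE)
  })
  skipped <- sum(vapply(rows, is.null, TRUE))
  if (skipped > 0L)
    message("enrichment: skipped ", skipped, " term(s) with < 2 background genes")
  res <- do.call(rbind, rows)
  if (is.null(res))
    return(data.frame(term_id = character(0), hits = integer(0),
                      subset_size = integer(0), term_size = integer(0),
                      background_size = integer(0), fold_enrichment = numeric(0),
                      pvalue = numeric(0), padj = numeric(0)))
  res$padj <- bh_adjust(res$pvalue)
  res[order(res$pvalue), , drop = FALSE]
}

#' Induced genes at a timepoint
#'
#' Collapses transcripts to genes: a gene counts as induced when any of its
#' transcripts is regulated, up, and changed by at least `lfc_cut` in log2.
#'
#' @param de DE table from [run_de()].
#' @param tx2gene Named character vector mapping transcript_id -> gene_id.
#' @param lfc_cut Absolute log2 fold-change cutoff (default 0.58).
#' @return Character vector of induced gene ids.
#' @export
induced_genes <- function(de, tx2gene, lfc_cut = 0.58) {
  sel <- de$regulated & de$log2fc >= lfc_cut
  unique(unname(tx2gene[de$transcript_id[sel]]))
}

#' Compare the acute and chronic timepoints
#'
#' Produces the acute-versus-chronic report: per-stratum counts of
#' transcripts at least 1.5-fold more or less expressed after chronic than
#' after acute treatment, the Venn partition of the induced gene sets, and
#' a gene table listing each induced gene with its acute and chronic log2
#' fold changes and its Venn subgroup (`a` = acute only, `b` = chronic
#' only, `c` = common).
#'
#' Chromatin gating is shared between timepoints: transcripts are scored
#' for H3K27me3 (unlesioned) and H3K27me3S28p (lesioned, acute) once and
#' those calls are reused for the chronic contrast.
#'
#' @param de_acute,de_chronic DE tables from [run_de()] over the same
#'   transcript universe.
#' @param gates Gate labels from [gate_subpopulations()] (acute mark
#'   calls).
#' @param tx2gene Named character vector, transcript_id -> gene_id.
#' @param lfc_cut Absolute log2 fold-change cutoff (default 0.58).
#' @return List: `stratum_shifts` (data.frame: stratum, n_more_chronic,
#'   n_less_chronic), `venn` (from [venn_counts()]), `gene_table`
#'   (data.frame: gene_id, log2fc_acute, log2fc_chronic, subgroup).
#' @export
compare_timepoints <- function(de_acute, de_chronic, gates, tx2gene,
                               lfc_cut = 0.58) {
  if (!setequal(de_acute$transcript_id, de_chronic$transcript_id))
    stop("acute and chronic DE tables cover different transcripts", call. = FALSE)
  ord <- match(de_acute$transcript_id, de_chronic$transcript_id)
  dc <- de_chronic[ord, ]
  stopifnot(identical(de_acute$transcript_id, gates$transcript_id))

  diff_lfc <- dc$log2fc - de_acute$log2fc
  strata <- list(double_positive = gates$stratum == "double_positive",
                 k27_only = gates$stratum == "k27_only",
                 all = rep(TRUE, nrow(gates)))
  shifts <- do.call(rbind, lapply(names(strata), function(s) {
    sel <- strata[[s]]
    data.frame(stratum = s,
               n_more_chronic = sum(sel & diff_lfc >= lfc_cut),
               n_less_chronic = sum(sel & diff_lfc <= -lfc_cut),
               stringsAsFactors = FALSE)
  }))

  genes_acute <- induced_genes(de_acute, tx2gene, lfc_cut)
  genes_chronic <- induced_genes(dc, tx2gene, lfc_cut)
  venn <- venn_counts(genes_acute, genes_chronic)

  all_genes <- union(genes_acute, genes_chronic)
  subgroup <- ifelse(all_genes %in% genes_acute & all_genes %in% genes_chronic, "c",
                     ifelse(all_genes %in% genes_acute, "a", "b"))
  gene_lfc <- function(de, gene) {
    sel <- tx2gene[de$transcript_id] == gene
    if (!any(sel)) return(NA_real_)
    v <- de$log2fc[sel]
    v[which.max(abs(v))]
  }
  gene_table <- data.frame(
    gene_id = all_genes,
    log2fc_acute = vapply(all_genes, function(g) gene_lfc(de_acute, g), 0),
    log2fc_chronic = vapply(all_genes, function(g) gene_lfc(dc, g), 0),
    subgroup = subgroup, stringsAsFactors = FALSE)
  rownames(gene_table) <- NULL
  list(stratum_shifts = shifts, venn = venn, gene_table = gene_table)
}
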