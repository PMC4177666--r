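#' Configuration for the differential-expression stage
#'
#' @param padj_cut BH-adjusted p-value cutoff for significance (default
#'   0.05).
#' @param lfc_cut Absolute log2 fold-change cutoff separating >= 1.5-fold
#'   changes from smaller ones (default 0.58, i.e. log2 of ~1.5).
#' @param detect_cut Detectability cutoff on the size-factor-normalized
#'   mean expression scale (default 0.004); transcripts whose larger group
#'   mean falls below it are considered non-detectable and never called
#'   regulated.
#' @param pseudocount Raw-count pseudocount guarding log fold changes at
#'   zero means (default 0.5).
#' @return A list of class `de_config`.
#' @export
de_config <- function(padj_cut = 0.05, lfc_cut = 0.58,
                      detect_cut = 0.004, pseudocount = 0.5) {
  stopifnot(padj_cut > 0, lfc_cut > 0, detect_cut > 0, pseudocount > 0)
  structure(list(padj_cut = padj_cut, lfc_cut = lfc_cut,
                 detect_cut = detect_cut, pseudocount = pseudocount),
            class = "de_config")
}

#' Median-of-ratios size factors
#'
#' Per-sample sequencing-depth factors: for each gene with all-positive
#' counts, the ratio of its count in a sample to its geometric mean across
#' samples; the sample's factor is the median of these ratios.
#'
#' @param counts Numeric matrix, transcripts x samples.
#' @return Numeric vector of size factors, one per sample (named if
#'   `counts` has colnames).
#' @examples
#' m <- matrix(c(10, 20, 30, 20, 40, 60), ncol = 2)
#' size_factors(m)  # ~ (1/sqrt(2), sqrt(2))
#' @export
size_factors <- function(counts) {
  counts <- as.matrix(counts)
  if (ncol(counts) < 2L) stop("need at least 2 samples", call. = FALSE)
  all_pos <- rowSums(counts > 0) == ncol(counts)
  if (!any(all_pos))
    stop("no gene has positive counts in every sample; ",
         "consider adding a pseudocount", call. = FALSE)
  lg <- log(counts[all_pos, , drop = FALSE])
  geo <- exp(rowMeans(lg))
  sf <- apply(counts[all_pos, , drop = FALSE] / geo, 2L, median)
  setNames(as.numeric(sf), colnames(counts))
}

#' Method-of-moments negative-binomial dispersion
#'
#' Per-gene dispersion alpha on size-factor-normalized counts, under the
#' NB variance model `var = mu + alpha * mu^2`. Within-condition means and
#' variances are computed per group, averaged across the two groups, and
#' alpha is the moment estimate floored at zero:
#' `alpha = max(0, (s2 - m) / m^2)`.
#'
#' @param counts Matrix, transcripts x samples.
#' @param factors Size factors from [size_factors()].
#' @param group Factor/vector of length `ncol(counts)` with two levels.
#' @return Numeric vector of per-gene dispersions (>= 0).
#' @export
estimate_dispersion <- function(counts, factors, group) {
  counts <- as.matrix(counts)
  group <- as.factor(group)
  if (nlevels(group) != 2L) stop("group must have exactly 2 levels", call. = FALSE)
  if (any(table(group) < 2L)) stop("need >= 2 replicates per condition", call. = FALSE)
  norm <- sweep(counts, 2L, factors, `/`)
  m <- s2 <- matrix(0, nrow(counts), 2L)
  for (i in 1:2) {
    sub <- norm[, group == levels(group)[i], drop = FALSE]
    m[, i] <- rowMeans(sub)
    s2[, i] <- apply(sub, 1L, var)
  }
  mbar <- rowMeans(m)
  s2bar <- rowMeans(s2)
  alpha <- (s2bar - mbar) / mbar^2
  alpha[!is.finite(alpha)] <- 0
  pmax(alpha, 0)
}

#' Negative-binomial Wald test for differential expression
#'
#' Tests each gene for a difference between two conditions. The statistic
#' is the difference of log normalized group means,
#' `delta = log(mB + c) - log(mA + c)` with pseudocount `c`, and its
#' variance comes from the delta method under the NB variance model
#' `Var(count) = mu + alpha * mu^2` evaluated at the per-sample fitted
#' means. Two-sided p-values are taken from the standard normal;
#' `log2fc = delta / ln 2`. Genes with both group means zero get
#' `p = 1`, `log2fc = 0` and are flagged.
#'
#' @param counts_A,counts_B Count matrices (genes x replicates) for the
#'   two groups, or vectors for a single gene.
#' @param factors_A,factors_B Size factors for the corresponding samples.
#' @param alpha Per-gene dispersion vector (recycled if length 1).
#' @param pseudocount Raw-count pseudocount (default 0.5).
#' @return data.frame with columns `norm_mean_A`, `norm_mean_B`, `log2fc`,
#'   `pvalue`, `flagged_zero`.
#' @export
nb_test <- function(counts_A, counts_B, factors_A, factors_B,
                    alpha = 0, pseudocount = 0.5) {
  if (is.null(dim(counts_A))) counts_A <- matrix(counts_A, nrow = 1L)
  if (is.null(dim(counts_B))) counts_B <- matrix(counts_B, nrow = 1L)
  if (ncol(counts_A) < 2L || ncol(counts_B) < 2L)
    stop("need >= 2 replicates per group", call. = FALSE)
  nA <- ncol(counts_A); nB <- ncol(counts_B)
  alpha <- rep_len(alpha, nrow(counts_A))
  mA <- rowMeans(sweep(counts_A, 2L, factors_A, `/`))
  mB <- rowMeans(sweep(counts_B, 2L, factors_B, `/`))
  c0 <- pseudocount
  delta <- log(mB + c0) - log(mA + c0)

  # Var(mean of count_ij/s_j) with Var(count_ij) = mu_ij + alpha mu_ij^2,
  # mu_ij = m * s_j  =>  contribution (m/s_j + alpha m^2) per sample.
  var_group <- function(m, s, n, a)
    (outer(m, 1 / s) + a * m^2) %*% rep(1, n) / n^2
  vA <- as.numeric(var_group(mA, factors_A, nA, alpha)) / (mA + c0)^2
  vB <- as.numeric(var_group(mB, factors_B, nB, alpha)) / (mB + c0)^2
  se <- sqrt(vA + vB)
  z <- ifelse(se > 0, delta / se, 0)
  p <- 2 * pnorm(-abs(z))
  zero <- mA == 0 & mB == 0
  p[zero] <- 1
  delta[zero] <- 0
  data.frame(norm_mean_A = mA, norm_mean_B = mB,
             log2fc = delta / log(2), pvalue = p,
             flagged_zero = zero)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment across a vector of p-values.
#' Thin validated wrapper around [stats::p.adjust()] with `method = "BH"`.
#'
#' @param pvalues Numeric vector, all values in \[0, 1\].
#' @return Adjusted p-values in input order.
#' @export
bh_adjust <- function(pvalues) {
  if (any(!is.na(pvalues) & (pvalues < 0 | pvalues > 1)))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  p.adjust(pvalues, method = "BH")
}

#' Run the full differential-expression stage on one contrast
#'
#' Size factors (median-of-ratios), method-of-moments dispersion, NB Wald
#' test, and BH correction, then regulation labelling via
#' [classify_regulated()].
#'
#' @param counts Matrix, transcripts x samples, rownames = transcript ids.
#' @param group Two-level factor over samples; the second level is the
#'   numerator of the fold change (use `factor(..., levels = c(A, B))`).
#' @param config A [de_config()].
#' @param exclusion_sets Optional list of transcript-id character vectors;
#'   members are never called regulated (auxiliary-contrast filters).
#' @return data.frame (one row per transcript): `transcript_id`,
#'   `norm_mean_A`, `norm_mean_B`, `log2fc`, `pvalue`, `padj`,
#'   `detectable`, `regulated`, `direction`, `fold_class`.
#' @export
run_de <- function(counts, group, config = de_config(),
                   exclusion_sets = list()) {
  counts <- as.matrix(counts)
  group <- as.factor(group)
  if (length(group) != ncol(counts))
    stop("group length must match the number of samples", call. = FALSE)
  sf <- size_factors(counts)
  alpha <- estimate_dispersion(counts, sf, group)
  selA <- group == levels(group)[1L]
  res <- nb_test(counts[, selA, drop = FALSE], counts[, !selA, drop = FALSE],
                 sf[selA], sf[!selA], alpha, config$pseudocount)
  res$transcript_id <- rownames(counts) %||% sprintf("tx%d", seq_len(nrow(counts)))
  res$padj <- bh_adjust(res$pvalue)
  classify_regulated(res, config, exclusion_sets)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Label transcripts as regulated, with detectability and exclusion filters
#'
#' Applies the regulation rules to a table of test results:
#' * `detectable`: the larger of the two normalized group means is at least
#'   `detect_cut`;
#' * `regulated`: `padj < padj_cut`, detectable, and not in any exclusion
#'   set;
#' * `direction`: `up` / `down` / `none` by the sign of `log2fc` for
#'   regulated transcripts;
#' * `fold_class`: `ge_1.5_up` / `ge_1.5_down` when `|log2fc| >= lfc_cut`,
#'   otherwise `sub_1.5`.
#'
#' @param results data.frame with columns `transcript_id`, `norm_mean_A`,
#'   `norm_mean_B`, `log2fc`, `pvalue`, `padj`.
#' @param config A [de_config()].
#' @param exclusion_sets List of transcript-id vectors to subtract.
#' @return `results` with the added label columns.
#' @export
classify_regulated <- function(results, config = de_config(),
                               exclusion_sets = list()) {
  stopifnot(inherits(config, "de_config"))
  excluded <- results$transcript_id %in% unique(unlist(exclusion_sets))
  detectable <- pmax(results$norm_mean_A, results$norm_mean_B) >= config$detect_cut
  regulated <- results$padj < config$padj_cut & detectable & !excluded
  results$detectable <- detectable
  results$regulated <- regulated
  results$direction <- ifelse(!regulated, "none",
                              ifelse(results$log2fc > 0, "up", "down"))
  results$fold_class <- ifelse(abs(results$log2fc) >= config$lfc_cut,
                               ifelse(results$log2fc > 0, "ge_1.5_up", "ge_1.5_down"),
                               "sub_1.5")
  cols <- c("transcript_id", "norm_mean_A", "norm_mean_B", "log2fc", "pvalue",
            "padj", "detectable", "regulated", "direction", "fold_class")
  extra <- setdiff(names(results), cols)
  results[, c(cols, extra)]
}
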