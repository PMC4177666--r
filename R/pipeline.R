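#' Run the full synthetic pipeline end to end
#'
#' Chains all stages on simulated data: annotation + truth, ChIP read
#' simulation for the H3K27me3 (unlesioned) and H3K27me3S28p (lesioned)
#' tracks, TSS-window quantitation, normal-fit mark calling, NB
#' differential expression for the acute (and optionally chronic)
#' timepoint, and joint gating. Mark calls are made once, from the acute
#' ChIP tracks, and reused for the chronic contrast.
#'
#' @param params A [sim_params()] object.
#' @param alpha Expected-by-chance rate for mark calling (default 0.05).
#' @param config A [de_config()].
#' @param fit_method Null-fit method, `"mle"` or `"robust"`.
#' @param timepoints Character vector, subset of `c("acute", "chronic")`.
#' @return List: `truth`, `transcripts`, `quant_k27`, `quant_s28p`,
#'   `fit_k27`, `fit_s28p`, `calls_k27`, `calls_s28p`, `de` (named list
#'   per timepoint), `gates` (per timepoint), `tx2gene`, and `comparison`
#'   (from [compare_timepoints()]) when both timepoints are run.
#' @export
run_pipeline <- function(params, alpha = 0.05, config = de_config(),
                         fit_method = c("mle", "robust"),
                         timepoints = c("acute", "chronic")) {
  fit_method <- match.arg(fit_method)
  timepoints <- match.arg(timepoints, several.ok = TRUE)
  ann <- simulate_annotation(params)
  windows <- tss_windows(ann$transcripts, params$flank)

  reads_k27 <- simulate_chip_reads(ann$transcripts, ann$truth, params,
                                   track = "H3K27me3", condition = "unlesioned")
  reads_s28 <- simulate_chip_reads(ann$transcripts, ann$truth, params,
                                   track = "H3K27me3S28p", condition = "lesioned")
  quant_k27 <- quantify_tss_signal(reads_k27, windows)
  quant_s28 <- quantify_tss_signal(reads_s28, windows)
  fit_k27 <- fit_null_normal(quant_k27$normalized, fit_method)
  fit_s28 <- fit_null_normal(quant_s28$normalized, fit_method)
  calls_k27 <- call_marks(quant_k27, fit_k27, alpha, mark = "H3K27me3")
  calls_s28 <- call_marks(quant_s28, fit_s28, alpha, mark = "H3K27me3S28p")

  tx2gene <- setNames(ann$truth$gene_id, ann$truth$transcript_id)
  de <- gates <- list()
  for (tp in timepoints) {
    counts <- simulate_rna_counts(ann$truth, params, timepoint = tp)
    grp <- factor(rep(c("unlesioned", "lesioned"), each = params$n_replicates),
                  levels = c("unlesioned", "lesioned"))
    de[[tp]] <- run_de(counts, grp, config)
    gates[[tp]] <- gate_subpopulations(calls_k27, calls_s28, de[[tp]],
                                       lfc_cut = config$lfc_cut)
  }
  out <- list(truth = ann$truth, transcripts = ann$transcripts,
              quant_k27 = quant_k27, quant_s28p = quant_s28,
              fit_k27 = fit_k27, fit_s28p = fit_s28,
              calls_k27 = calls_k27, calls_s28p = calls_s28,
              de = de, gates = gates, tx2gene = tx2gene)
  if (all(c("acute", "chronic") %in% timepoints))
    out$comparison <- compare_timepoints(de$acute, de$chronic, gates$acute,
                                         tx2gene, lfc_cut = config$lfc_cut)
  out
}
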