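make_calls <- function(ids, positive, mark = "m") {
  data.frame(transcript_id = ids, mark = mark, signal = as.numeric(positive),
             positive = positive, threshold = 0.5, alpha = 0.05,
             stringsAsFactors = FALSE)
}

make_de <- function(ids, log2fc, regulated = rep(TRUE, length(ids))) {
  data.frame(transcript_id = ids, norm_mean_A = 100, norm_mean_B = 100,
             log2fc = log2fc, pvalue = 0.001,
             padj = ifelse(regulated, 0.01, 0.5),
             detectable = TRUE, regulated = regulated,
             direction = ifelse(!regulated, "none", ifelse(log2fc > 0, "up", "down")),
             fold_class = ifelse(abs(log2fc) >= 0.58,
                                 ifelse(log2fc > 0, "ge_1.5_up", "ge_1.5_down"),
                                 "sub_1.5"),
             stringsAsFactors = FALSE)
}

test_that("gating assigns the six subpopulations from marks and fold change", {
  ids <- c("dp_up", "dp_dn", "k27_up", "k27_dn", "un_up", "un_dn",
           "small", "notreg")
  k27 <- make_calls(ids, c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE, TRUE, TRUE))
  s28 <- make_calls(ids, c(TRUE, TRUE, FALSE, FALSE, FALSE, FALSE, TRUE, TRUE))
  de <- make_de(ids, c(1, -1, 1, -1, 1, -1, 0.2, 1),
                regulated = c(rep(TRUE, 7), FALSE))
  g <- gate_subpopulations(k27, s28, de)
  expect_equal(g$subpopulation,
               c("II", "I", "IV", "III", "VI", "V", "none", "none"))
  expect_equal(g$stratum[1:6],
               c("double_positive", "double_positive", "k27_only", "k27_only",
                 "unmarked", "unmarked"))
  # strata are disjoint and every K27+ regulated transcript is in exactly one
  expect_false(any(g$stratum == "double_positive" & g$stratum == "k27_only"))
  # V/VI count over ALL regulated transcripts, including those in I-IV
  counts <- subpopulation_counts(g)
  expect_equal(unname(counts),
               c(1L, 1L, 1L, 1L, 3L, 3L))
  # missing ids are an error
  expect_error(gate_subpopulations(k27[-1, ], s28, de), "missing")
})

test_that("induced fraction reproduces the printed stratum percentages", {
  expect_equal(fraction_induced(339, 52), 87L)   # double-positive stratum
  expect_equal(fraction_induced(332, 230), 59L)  # K27me3-only stratum
  expect_equal(fraction_induced(2892, 844), 77L) # all regulated transcripts
  expect_equal(fraction_induced(10, 10), 50L)
  # half-up rounding: 0.5% boundaries round up
  expect_equal(fraction_induced(1, 7), 13L)  # 12.5 -> 13
  expect_warning(out <- fraction_induced(0, 0), "undefined")
  expect_true(is.na(out))
})

test_that("venn counts partition the two gene sets", {
  A <- sprintf("g%03d", 1:96)
  B <- c(sprintf("g%03d", 1:43), sprintf("h%03d", 1:71))
  expect_equal(venn_counts(A, B),
               c(exclusive_A = 53L, common = 43L, exclusive_B = 71L))
  expect_equal(venn_counts(c("a", "b"), c("c")),
               c(exclusive_A = 2L, common = 0L, exclusive_B = 1L))
  expect_equal(venn_counts(A, A),
               c(exclusive_A = 0L, common = 96L, exclusive_B = 0L))
  # partition identity on random sets
  set.seed(7)
  for (i in 1:5) {
    X <- sample(letters, 10); Y <- sample(letters, 12)
    v <- venn_counts(X, Y)
    expect_equal(v[["exclusive_A"]] + v[["common"]], length(unique(X)))
    expect_equal(v[["exclusive_B"]] + v[["common"]], length(unique(Y)))
  }
})

test_that("2D histograms bin points exactly once", {
  # 4 hand-placed points on a 2x2 grid
  h <- histogram2d(x = c(0.1, 0.9, 0.9, 0.6), y = c(0.1, 0.1, 0.9, 0.8),
                   x_bins = c(0, 0.5, 1), y_bins = c(0, 0.5, 1))
  expect_equal(h$counts, matrix(c(1L, 1L, 0L, 2L), 2))
  # edge membership: last bin is closed, so a point at the max lands inside
  h2 <- histogram2d(c(0, 1), c(0, 1), c(0, 0.5, 1), c(0, 0.5, 1))
  expect_equal(sum(h2$counts), 2L)
  # one point -> exactly one nonzero cell
  h3 <- histogram2d(0.3, 0.3, 4L, 4L)
  expect_equal(sum(h3$counts), 1L)
  expect_equal(sum(h3$counts > 0), 1L)
  # conservation on random data, non-finite dropped with a message
  set.seed(8)
  x <- c(rnorm(500), NA, Inf); y <- c(rnorm(500), 1, 1)
  expect_message(h4 <- histogram2d(x, y, 10L, 7L), "dropped 2")
  expect_equal(sum(h4$counts), 500L)
  expect_error(histogram2d(1:3, 1:3, c(0, 0, 1)), "increasing")
})

test_that("hypergeometric enrichment matches the exact combinatorial sum", {
  bg <- sprintf("g%03d", 1:100)
  term <- bg[1:10]
  subset <- c(bg[1:5], bg[50:54])  # 5 hits out of 10 drawn
  res <- enrichment(subset, list(T1 = term), bg)
  expect_equal(res$hits, 5L)
  expect_equal(res$fold_enrichment, (5 / 10) / (10 / 100))  # 5.0
  expect_equal(res$pvalue, brute_hyper_upper(5, 10, 100, 10))

  # random instances with background <= 200
  set.seed(9)
  for (i in 1:10) {
    N <- sample(50:200, 1)
    bgi <- sprintf("x%04d", seq_len(N))
    m <- sample(2:20, 1); k <- sample(5:30, 1)
    termi <- sample(bgi, m)
    sub <- sample(bgi, k)
    r <- enrichment(sub, list(t = termi), bgi)
    h <- length(intersect(sub, termi))
    expect_equal(r$pvalue, brute_hyper_upper(h, m, N, k))
    expect_equal(r$fold_enrichment, (h / k) / (m / N))
  }

  # subset = background: fold 1 and p 1 for every term
  r_all <- enrichment(bg, list(T1 = term, T2 = bg[20:40]), bg)
  expect_equal(r_all$fold_enrichment, c(1, 1))
  expect_equal(r_all$pvalue, c(1, 1))
  # no hits: fold 0, p 1
  r0 <- enrichment(bg[90:99], list(T1 = bg[1:10]), bg)
  expect_equal(r0$fold_enrichment, 0)
  expect_equal(r0$pvalue, 1)
  # undersized terms are skipped with a message
  expect_message(rs <- enrichment(bg[1:5], list(tiny = bg[1], ok = bg[1:10]), bg),
                 "skipped 1")
  expect_equal(rs$term_id, "ok")
  expect_error(enrichment(c("zz"), list(t = bg[1:5]), bg), "contained")
  expect_error(enrichment(character(0), list(t = "a"), character(0)), "empty")
})

test_that("the reported worked enrichment example is reproduced", {
  # a 5-gene hit in a 93-gene term from a ~200-gene subset of a large
  # background gives a strong fold enrichment; exact numbers depend on the
  # universe, checked here on a synthetic instance with the same shape
  bg <- sprintf("g%05d", 1:20000)
  term <- bg[1:93]
  subset <- c(bg[1:5], bg[10000:10204])  # 210 genes, 5 in the term
  r <- enrichment(subset, list(adult_behavior = term), bg)
  expect_equal(r$hits, 5L)
  expect_equal(r$fold_enrichment, (5 / 210) / (93 / 20000), tolerance = 1e-12)
  expect_lt(r$pvalue, 0.01)
})

test_that("timepoint comparison reports shifts, venn and subgroups", {
  ids <- sprintf("tx%02d", 1:6)
  genes <- setNames(sprintf("g%02d", 1:6), ids)
  k27 <- make_calls(ids, rep(TRUE, 6))
  s28 <- make_calls(ids, c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE))
  # identical acute and chronic: venn (0, n, 0), all differences 0
  de <- make_de(ids, c(1, 2, 1, 1, 1, 1))
  g <- gate_subpopulations(k27, s28, de)
  cmp <- compare_timepoints(de, de, g, genes)
  expect_equal(unname(cmp$venn), c(0L, 6L, 0L))
  expect_true(all(cmp$stratum_shifts$n_more_chronic == 0))
  expect_true(all(cmp$stratum_shifts$n_less_chronic == 0))
  expect_true(all(cmp$gene_table$subgroup == "c"))

  # one gene induced 2-fold acute and 4-fold chronic: subgroup c, both lfc
  de_a <- make_de(ids, c(1, 0, 0, 0, 0, 0), regulated = c(TRUE, rep(FALSE, 5)))
  de_c <- make_de(ids, c(2, 0, 0, 0, 0, 0), regulated = c(TRUE, rep(FALSE, 5)))
  cmp2 <- compare_timepoints(de_a, de_c, gate_subpopulations(k27, s28, de_a), genes)
  expect_equal(unname(cmp2$venn), c(0L, 1L, 0L))
  row <- cmp2$gene_table[cmp2$gene_table$gene_id == "g01", ]
  expect_equal(row$subgroup, "c")
  expect_equal(row$log2fc_acute, 1)
  expect_equal(row$log2fc_chronic, 2)
  # chronic 1.5-fold above acute shows up as a per-stratum shift
  expect_equal(cmp2$stratum_shifts$n_more_chronic[
    cmp2$stratum_shifts$stratum == "double_positive"], 1L)
  expect_error(compare_timepoints(de_a, de_c[-1, ], g, genes), "different")
})
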