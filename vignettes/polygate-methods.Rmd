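---
title: "Methods: mark calling, differential expression, and joint gating"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mark calling, differential expression, and joint gating}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(polygate)
```

## Overview

`polygate` classifies transcripts jointly by promoter-proximal chromatin
state and transcriptional response. The motivating setting is the
hemiparkinsonian mouse striatum, where L-DOPA triggers phosphorylation of
serine 28 on histone H3 tails already carrying the Polycomb mark H3K27me3
(the dual mark H3K27me3S28p) and derepresses Polycomb target genes. The
pipeline has four stages:

1. **TSS-window quantitation** of ChIP-seq signal with library-size and
   region-size normalization;
2. **mark calling** by fitting a normal distribution to the genome-wide
   signal and thresholding at an expected-by-chance rate;
3. a minimal **negative-binomial differential-expression** stage;
4. **joint gating** of regulated transcripts into chromatin-defined
   subpopulations, with acute-versus-chronic comparison and hypergeometric
   term enrichment.

A synthetic-data generator with planted truth makes every stage testable
without any external data.

## Signal quantitation

For each transcript the window spans `flank` bp (default 1000) on each side
of the TSS — the annotated start for `+` strand transcripts, the annotated
end for `-` strand ones. The signal is the number of reads overlapping the
window by at least 1 bp, normalized to reads per 1 kbp per 10 million
reads:

$$ s_i = c_i \cdot \frac{10^7}{N} \cdot \frac{1000}{w_i} $$

with $c_i$ the raw overlap count, $N$ the library size and $w_i$ the window
width in bp. Windows are clamped at chromosome edges, so $w_i$ can fall
below $2\,\mathrm{flank}$ there; the normalization uses the realized width.

Two counting rules are available (`mode = "overlap"` / `"fivep"`). The
default counts any overlap, which matches how the bedGraph track export
counts reads in bins — one rule throughout the package. Reads are not
shifted or extended toward fragment centers: the 2-kb window is large
relative to typical fragment-size offsets, so the correction would be
cosmetic. Quantitation is per transcript; transcripts sharing a TSS are
deliberately not collapsed, since the transcript is the unit of analysis
downstream.

An optional second normalization, `h3_normalize()`, divides a mark's signal
by a total-H3 track quantified over the same windows, correcting for
nucleosome density. Transcripts with zero H3 signal get an undefined ratio
and are flagged for exclusion on that axis. Gating in `run_pipeline()` uses
the library-normalized scale, on which automatic thresholds are defined;
which axis was used is recorded in the call provenance.

## Mark calling

A normal distribution is fitted to the normalized signal of *all*
transcripts genome-wide — enriched loci included, which is the literal
procedure this stage reproduces. The automatic threshold at
expected-by-chance rate $\alpha$ (default 0.05) is the upper $\alpha$
quantile of the fitted null:

$$ t = \hat\mu + \hat\sigma \, z_{1-\alpha} $$

A transcript is positive iff its signal strictly exceeds $t$; ties are
negative (a conservative, deterministic rule). The fit is on raw normalized
signals, no log transform, because published thresholds on this scale are
raw-valued; a robust alternative (`method = "robust"`, median and
1.4826×MAD) is provided because the enriched tail inflates the MLE
$\hat\sigma$ when the marked fraction is large. The default stays `"mle"`:
fidelity to the described procedure first, robustness opt-in. With ~20%
marked loci at 8-fold enrichment the MLE fit still recovers over 90% of
planted positives, so the default is adequate across the regimes the tests
exercise.

Degenerate input (constant signal, $\hat\sigma = 0$) yields a flagged fit
whose threshold equals $\hat\mu$, with a warning rather than an error.

## Differential expression

The DE stage is a deliberately minimal negative-binomial test — the
analysis it stands in for treats DE as a black box, and downstream gating
needs only a fold change and an adjusted p-value per transcript.

* **Size factors** are median-of-ratios: for genes with all-positive
  counts, $f_j = \mathrm{median}_g \left( c_{gj} / (\prod_k c_{gk})^{1/m} \right)$.
* **Dispersion** is a per-gene method-of-moments estimate on normalized
  counts, $\hat\alpha = \max\!\big(0, (\bar{s^2} - \bar m)/\bar m^2\big)$,
  with within-condition means and variances averaged across the two
  conditions.
* **The test** is a Wald test on
  $\Delta = \log(\hat m_B + c) - \log(\hat m_A + c)$ with a pseudocount of
  $c = 0.5$ raw counts guarding zero means, variance from the delta method
  under $\mathrm{Var}(K) = \mu + \alpha\mu^2$, two-sided p-values from the
  standard normal, and $\log_2\!\mathrm{FC} = \Delta/\ln 2$. Genes with
  both group means zero get $p = 1$ and a flag.
* **Multiple testing** is Benjamini–Hochberg across all transcripts.

A transcript is *regulated* when its BH-adjusted p is below `padj_cut`
(default 0.05), it is detectable, and it is not in a user-supplied
exclusion set (the mechanism for removing genes that also respond in
auxiliary control contrasts, e.g. treatment effects in the unlesioned
hemisphere). Fold classes split at `lfc_cut = 0.58` in log2 units, i.e.
1.5-fold.

**Detectability scale.** The detectability cutoff (default 0.004) is
applied to the size-factor-normalized mean expression of the transcript,
`max(norm_mean_A, norm_mean_B)`. A relative-abundance reading (dividing by
the matrix grand total) was considered and rejected: per-transcript
relative abundance is of order $1/n_\mathrm{transcripts}$, so any fixed
cutoff of magnitude 0.004 would classify essentially every transcript as
non-detectable at realistic problem sizes. On the normalized-count scale
the default only removes essentially silent transcripts; the cutoff is
configurable for data whose upstream normalization differs.

**Known limitation.** With three replicates and no dispersion shrinkage
(shrinkage toward a fitted trend is out of scope), the per-gene moment
estimate is noisy and frequently floors at zero, making the Wald test
anti-conservative: on null NB data at dispersion 0.05 and mean 200, the
realized type-I error at nominal 0.05 is about 0.05 when the generating
dispersion is supplied but rises to roughly 0.12 with the plug-in estimate.
Consumers who need tight error control on real data should use a mature DE
package and feed its `(log2fc, padj)` into the gating stage, which accepts
any table with those columns.

## Joint gating

H3K27me3 status is taken from the **unlesioned** hemisphere — S28
phosphorylation masks the K27me3 epitope, so calling K27me3 in the lesioned
tissue would undercount true double-marked loci — and H3K27me3S28p status
from the **lesioned** hemisphere after acute treatment. Chronic-timepoint
gating reuses the acute mark calls: the chromatin assignment is made once.

Regulated transcripts with $|\log_2\mathrm{FC}| \ge 0.58$ receive a
subpopulation: I (down) / II (up) at K27me3+S28p+ loci, III/IV at
K27me3+S28p− loci, V/VI over all regulated transcripts regardless of
chromatin (so a transcript labelled II also counts toward VI;
`subpopulation_counts()` applies that convention). The induced fraction of
a stratum is $100\,u/(u+d)$ rounded half-up — the rounding rule that maps
339 up / 52 down to 87%.

For acute-versus-chronic comparison, transcripts are collapsed to genes: a
gene is *induced* if any of its transcripts is regulated, up, and at least
1.5-fold changed. Any-transcript collapse is the permissive, deterministic
choice; the Venn partition of the two induced-gene sets and per-stratum
counts of transcripts shifted by at least 1.5-fold between timepoints make
up the report, together with a gene table labelling each induced gene
`a` (acute only), `b` (chronic only) or `c` (common).

Term enrichment is a hypergeometric upper tail on a user-supplied term map:
fold enrichment $(h/k)/(m/N)$ and $p = P[X \ge h]$, BH-corrected across
terms. Terms with fewer than two background genes are skipped to avoid
degenerate fold estimates.

## The synthetic-data generator

`simulate_annotation()` places non-overlapping transcripts on one synthetic
chromosome, one per 5-kb slot, and draws planted truth: K27me3 status
(default 20% of loci), S28p gain among K27me3+ loci (default 40%), and
planted log2 fold changes (default: 10% of transcripts regulated per
timepoint, magnitudes from {0.6, 1, 1.5, 2, 3} with random signs).
`simulate_chip_reads()` adds uniform background reads at a density giving
20 expected reads per 2-kb window by default, plus Poisson extras at
positive loci so the window count is Poisson with mean
`background_rate * enrichment_fold` (default 8-fold). Reads are 36 bp —
the read length of the sequencer generation this emulates — and placed
uniformly within enriched windows, with no peak shape: window-sum
quantitation is shape-insensitive, so a peak model would add parameters
without adding test power. `simulate_rna_counts()` draws NB counts for
triplicates of two conditions with per-sample library-size multipliers
log-uniform in [0.5, 2], wide enough to exercise the median-of-ratios
correction nontrivially.

The generator does **not** emulate GC bias, duplicate reads, fragment-size
variation, mappability gaps, overdispersed (non-Poisson) ChIP backgrounds,
or correlated transcript structure within genes (it plants one transcript
per gene). Passing recovery tests therefore demonstrate that the
*computational* stages are correct and calibrated under their stated
models, not that the models capture every failure mode of real sequencing
data.

## Numerical and scale choices

* Intervals are `GRanges` (1-based, closed) throughout; BED (0-based
  half-open) and GTF (1-based closed) are converted at the I/O boundary by
  `rtracklayer`, so one convention holds everywhere in memory.
* The null-calibration experiment uses 20,000 transcripts with a Poisson
  window mean of 100: large enough that the normal fit's error and the
  binomial sampling error together stay well inside ±1.5 percentage points
  of the 5% target; it completes in seconds.
* Recovery experiments use 2,000–4,000 transcripts and the default
  enrichment/expression settings above; unit-level Monte-Carlo oracles use
  3 binomial/Poisson SDs as tolerance, plus an explicit edge-correction
  term where overlap counting catches reads straddling window boundaries.
* Seeds: every generator derives its stream from one master seed, so whole
  pipelines are byte-reproducible; per-generator offsets keep streams
  decoupled when a subset is re-run.
* Ties at the mark threshold are negative; BH is `stats::p.adjust`;
  hypergeometric tails are `stats::phyper` (exact combinatorial sums serve
  as test oracles, not as the implementation).
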