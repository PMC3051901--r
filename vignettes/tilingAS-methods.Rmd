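---
title: "Detecting alternative splicing from tiling arrays: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting alternative splicing from tiling arrays: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the statistical model behind `tilingAS`, the
parameters a user may want to touch, what the synthetic-data generator does
and does not emulate, and the design decisions taken where the method
description left genuine freedom. It states no empirical result that the
package's tests and acceptance script do not themselves compute.

## 1. The measurement model

A whole-genome tiling array measures fluorescence of 25-mer probes spaced
~35 bp center-to-center. For a gene segment $s$ (an exon or intron of a gene
$g$) interrogated by probes $p_1,\dots,p_n$ in sample $t$ with three
replicates, the data are the $3n$ log2 intensities $I_{tr}(p_j)$. Exonic
probes report transcript abundance (declining toward the 5' end of the
transcript because of 3'-biased labeling); intronic probes report a
background that still grows with expression (incomplete splicing,
cross-hybridization). A retained intron hybridizes exon-like in the samples
where it is included; a skipped exon hybridizes intron-like. Inclusion is
therefore a per-(segment, sample) quantity, and AS detection is a two-level
inference: estimate inclusion per sample, then integrate across samples.

## 2. Event definitions

Events are defined on per-gene splicing graphs (exons = nodes, introns =
edges, built from annotation plus EST/cDNA exon structures merged by genomic
overlap on the same strand):

* **IR**: an intron spliced out of at least one isoform while another
  isoform has an exon spanning the complete intron interval.
* **ES**: an exon present in at least one transcript and entirely contained
  in an intron of another transcript, the two transcripts sharing at least
  one exon on each side.

Containment is exact interval arithmetic on 0-based half-open coordinates;
the GFF3/tab readers are the only code performing the 1-based shift.
Alternative 5'/3' splice sites are out of scope: at 35 bp pitch most such
events touch a single probe.

## 3. Stage 1: expression-stratified exon/intron SVMs

Features per (segment, sample):

* `f_abs` — five local percentiles (P20, P40, P50, P60, P80) of the $3n$
  pooled intensities. One percentile convention (linear interpolation
  between closest order statistics, R type 7) is used package-wide; the
  duplicated median in the percentile list is kept exactly as specified.
* `f_rel` — a soft histogram over five global percentiles $L$ of all genic
  probe intensities. Each measurement contributes one unit of weight: all of
  it to the first (last) bin if $I \le L_1$ ($I \ge L_N$), otherwise split
  $\alpha = (L_{k+1}-I)/(L_{k+1}-L_k)$ / $1-\alpha$ between the two
  enclosing bins. The printed piecewise definition does not cover
  $I = L_N$; we close that gap by continuity (full weight on the last bin).
  Components sum to $3n$ exactly — a tested conservation law.
* `f_pos` — the same interpolation applied to probe distances to the 3'
  transcript end, limits (100, 300, ..., 1900) nt, one unit per probe
  (position does not vary across replicates). Distances are spliced-transcript
  distances on the longest isoform; probes inside introns of that isoform use
  the genomic projection (introns counted), since the paper-level description
  is silent about intronic probes and they need positional features too.

Training pairs are constitutive exons (+1) and introns (−1) not present in
the SCS benchmark. Because the exon/intron contrast grows with expression,
ten linear soft-margin SVMs are trained, one per decile of the per-gene
per-sample median exonic intensity (limits P10..P90). The published 60/20/20
train/validation/test split at 5 folds is realized as 3+1+1 rotating folds;
folds are assigned at the segment level so no segment leaks across roles.
C is selected per bin per fold from {0.001, ..., 1000} on the validation
fold; the final per-bin model is refit on all pairs with the modally chosen
C. The solver is this package's own dual coordinate descent for the
L2-regularized hinge loss (no SVM library is assumed); the bias is an
augmented constant feature. Features are standardized per bin on the
training data — the method description is silent, and a grid-searched linear
SVM expects comparable feature scales.

Scores become probabilities through a monotone piecewise-linear calibration:
isotonic regression of labels on out-of-fold scores, then linear
interpolation between block centers, clipped to [0,1]. Calibration is per
bin (the ten SVMs are differently parametrized, so their scores are not
comparable); anti-correlated inputs are rejected with a warning, and a bin
that degenerates to one class falls back to a constant scorer at the bin's
prevalence.

## 4. Stage 2: integration, FDR, differential scores

For each segment the inclusion vector over the 24 samples is sorted in
descending order (stable, ties by original sample index) and concatenated
with the flanking-exon median expression permuted by the same order, giving
a 48-dimensional vector in which "how many samples include this segment at
what expression" is positionally encoded. Separate linear SVMs are trained
for IR (on the intron SCS set) and ES (exon SCS set) by 5-fold CV; the
out-of-fold scores calibrate confidences and set the score cutoff at target
empirical FDR 0.5 (IR) / 0.7 (ES). Segments missing more than 20% of
samples are excluded; the remainder are mean-imputed before sorting and
flagged.

Differential splicing uses the stage-1 probabilities directly:
$S_\mathrm{tissue} = \max_t p - \min_t p$ over the 11 tissues and
$S_\mathrm{stress} = \max_{(t,c)} |p_t - p_c|$ over treatment/control
pairs from the sample sheet. The reference set for the recall-0.1 flag
cutoffs is not stated in the method description; we use the SCS positives.

## 5. Baselines

* **ANOVA splicing index.** Each sample is a group holding the segment's
  $3n$ probe×replicate splicing indices $S_t(s) = I_t(s)/m_t(g)$ (linear
  ratio, as defined); the one-way fixed-effects F-test is applied to their
  log2 by default. Rationale: the splicing index is introduced as a
  *logarithmized* expression ratio, the noise model is additive on the log
  scale, and the F-test is exactly calibrated there. Groups are
  probe×replicate values, an acknowledged pseudo-replication that mirrors
  the original construction.
* **Modified Ner-Gaon scoring.** Welch mean comparisons (on log2) of the
  tested intron against the pooled other introns and the pooled exons of
  the same gene, at significance level $\alpha$; class encoding 4 =
  higher-than-introns and similar-to-exons, 3 = higher-than-introns but
  below exons, 2 = similar to both, 1 = similar-to-introns only, 0 =
  undifferentiated (including single-intron genes and fully degenerate
  data). The only hard constraint on the encoding is that the index grows
  with IR confidence; the exact original taxonomy lives in a reference not
  reproduced here, so this mapping is a documented stand-in. The score is
  $N(s) = \max_\alpha c(s,\alpha) + (1-\alpha)$ over five log-spaced
  $\alpha \in [0.01, 0.5]$, no multiple-testing correction, no minimum
  probe count, no intensity cutoffs.

Both baselines emit the same table schema as the stage-2 detector
(score = $-\log_{10} p$ or $N(s)$), so the evaluation utilities consume all
three uniformly.

## 6. RNA-seq IR calling and overlaps

From merged per-base coverage, an annotated intron is called retained iff
(a) median coverage > 2 (strict), (b) ≥75% of bases covered by ≥1 read, and
(c) mean coverage within 10–120% of the flanking-exon average, flanks within
4-fold of each other (all inclusive, exactly as worded). Aligners are out of
scope; the module ingests bedGraph. Overlaps of event sets are summarized by
the representation factor $O\,N/(n_1 n_2)$ and the hypergeometric upper-tail
p-value.

## 7. The synthetic world

The generator emulates what the detector needs and nothing more:

* geometry: 5-exon/4-intron genes (the average gene shape used by the
  composition arithmetic), log-normal exon/intron lengths around 160 bp,
  25-mer probes at 35 ± 3 bp pitch;
* design: 24 samples = 11 tissues + 11 stress treatments paired to 2 shared
  controls (the published 24-sample design cannot contain 13 disjoint
  treatment/control pairs), 3 replicates;
* signal: per-gene log2 expression $\mu_g \sim N(8, 1.5^2)$ with per-sample
  jitter 0.25 (stress treatments copy their control's expression exactly, so
  planted stress events differ only in inclusion); exon signal
  $\mu_{gt} - 0.3\,d_{3'}/\mathrm{kb}$; intron background
  $2.5 + 0.25\,\mu_{gt}$; per-probe affinity offsets $N(0, 0.5^2)$ (what
  transcript normalization removes); replicate noise $N(0, 0.8^2)$ — values
  chosen once as representative of Affymetrix tiling data and not revisited;
* events: 30% of genes carry one AS event (IR:ES ≈ 0.79:0.21, following the
  observed 996:259 event ratio); 40% of events are differential (half
  tissue-restricted, half stress-responsive), inclusion levels 0.9/0.1
  against a basal 0.5; a planted segment's signal is the linear mixture
  $\log_2[(1-\rho)2^{bg} + \rho\,2^{sig}]$;
* evidence: per-gene Poisson transcript counts with rate proportional to
  linear expression (mean 12), 20% full-length cDNAs, ESTs covering random
  exon windows; isoform choice follows the event's mean inclusion;
* coverage: piecewise-constant per segment, exact under the noiseless
  preset, per-chunk Poisson otherwise.

Three presets ship: `default` (above), `easy` (all noise off, inclusion
0/1 — for exactness tests: the noiseless limit must give stage-1 auROC
exactly 1 and every fully retained intron must pass the RNA-seq filter), and
`null` (no AS, no probe effects, no per-sample expression variation,
near-noiseless exonic medians — the exact null of the ANOVA baseline).

What a green test does **not** establish: the generator has no
cross-hybridization beyond the repetitive-probe flag, no chip-spatial
artifacts, no saturation or probe-sequence (GC/Tm) effects, no alternative
5'/3' events, and its label noise structure (planted AS segments keep their
annotation label in stage-1 training, exactly as with real annotation) is
milder than reality. Recovery numbers on simulation are upper bounds on real
data, which is why the published genome-wide counts are explicitly not
reproduction targets.

On the null preset a remark is in order: a Kolmogorov–Smirnov uniformity
check of ANOVA p-values is only meaningful under the test's exact null.
Nuisance variance in the per-sample gene-expression median shifts whole
sample groups coherently and inflates the F statistic even without any
splicing signal — that is a property of the splicing-index construction, not
an implementation error — so the null preset gives the gene-expression
estimate negligible noise (`sd_e = 0.05`) while keeping the intron noise at
its default.

## 8. Numerical choices and degenerate inputs

* Percentiles: type-7 interpolation everywhere; stated once, reused.
* Interpolation boundaries: first-match-wins in the printed case order, so
  $I = L_1$ lands in bin 1; $I = L_N$ (uncovered by the printed cases) lands
  in bin N by continuity; duplicated limits cannot produce zero-width
  divisions because the interval search skips past them.
* Quantile normalization maps every array to the mean of the sorted columns;
  ties receive the mean of the corresponding reference values; the operation
  is idempotent (tested).
* Transcript (probe-effect) normalization subtracts the per-probe median
  deviation from the gene's per-sample median exonic intensity — for exonic
  probes only. Applying the same correction to intronic probes would
  subtract the exon−intron gap itself and erase the classes stage 1
  separates; the underlying probe-affinity model is only identified for
  probes that measure the transcript.
* Ties in ranking: ROC/PR move all equally scored items together; the FDR
  cutoff is the smallest score whose tail FDR meets the target; the recall
  cutoff is the largest score retaining the target fraction of positives.
* Degenerate SVM bins fall back to constant scorers with warnings; stage-2
  fold counts shrink when positives are scarce (warned), and with fewer than
  three folds C is selected on the training fold itself.
* Seeds: every stochastic step takes an explicit seed; child seeds are
  derived arithmetically and kept below $2^{31}$.

## 9. Known limitations

* The ES detector inherits the hard 1:84 class imbalance and, as in the
  original study, is substantially weaker than IR detection; the pipeline
  skips it (with a warning) when fewer than 10 sequence-confirmed positives
  exist.
* The spatial background correction is a simplified grid-local mean,
  disabled by default; CEL decoding, BLAT/Palmapper alignment and mismatch
  probes are out of scope by design.
* `count_confirmations` requires exact junction coordinates; evidence from a
  different assembly must be lifted over beforehand.
* The calibration stand-in (isotonic + interpolation) satisfies the
  "monotone piecewise linear" contract but is not the referenced original
  algorithm.
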