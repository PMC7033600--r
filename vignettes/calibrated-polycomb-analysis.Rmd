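---
title: "Spike-in calibrated analysis of Polycomb chromatin data with polycalib"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spike-in calibrated analysis of Polycomb chromatin data with polycalib}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(polycalib)
```

# The problem

Conventional ChIP-seq and RNA-seq normalization assumes that most of the
signal is unchanged between conditions: library-size or median-of-ratios
scaling maps each sample onto a common "typical" signal level.  When a
perturbation removes a chromatin mark *globally* — for instance, loss of
PRC1 catalysis eliminating H2AK119ub1 genome-wide — that assumption is
exactly wrong, and conventional normalization silently rescales the loss
away.  The remedy is an internal standard: a fixed proportion of foreign
("spike-in") cells is mixed into every sample before library preparation, so
that reads aligning to the spike-in genome provide an absolute, per-cell
anchor that is immune to changes in target-genome signal.

`polycalib` implements this calibrated analysis stack end to end:

* **calibration** — per-sample calibration factors with correction for minor
  variations in cell mixing, applied by read subsampling or deterministic
  coverage scaling;
* **differential** — spike-anchored size factors feeding a per-region
  negative-binomial Wald test, including the two-factor (cell line x
  treatment) interaction design;
* **genome_intervals** — genome tiling, interval counting, signal scaling
  and expression-percentile profiles;
* **polycomb_classification** — peak reproducibility/blacklist/signal-loss
  filtering and the Non-NMI / Non-PcG / PcG promoter classification with
  PRC1-repressed and full/partial derepression calls;
* **capturec_quant** — in-silico DpnII digestion, capture normalization, and
  interaction-peak merging/quantification;
* **foci3d** — 3D segmentation and quantification of nuclear Polycomb
  bodies;
* **synthetic_data** — generators for every input above with known ground
  truth.

# The calibration model

Let $C_t^{(i)}$ and $C_s^{(i)}$ be the target- and spike-genome read tallies
of ChIP/RNA sample $i$, and let its matched input (or genomic DNA) sample
have tallies $I_t^{(i)}, I_s^{(i)}$.  Because input libraries sample DNA in
proportion to cell content, independent of immunoprecipitation,

$$r_i = I_s^{(i)} / I_t^{(i)}$$

estimates the achieved spike-to-target cell-mixing ratio of that particular
sample.  The mixing-corrected effective spike depth and the downsampling
fraction are

$$S_i = C_s^{(i)} / r_i, \qquad f_i = \min_j S_j \, / \, S_i,$$

so the sample with the smallest corrected spike depth keeps all of its reads
and every sample ends up with the same expected spike depth per cell
(`computeCalibration()`).  Bernoulli subsampling of target reads with
probability $f_i$ (`downsampleReads()`) produces calibrated coverage; a
deterministic per-read weight is available instead (`mode = "scale"`) when
exact reproducibility of coverage tracks matters more than read-level
output.

For differential testing the same anchor enters as a size factor instead of
a subsampling step: spike-genome counts at a control interval set are
pre-divided by $r_i / \tilde r$ (geometric-mean-centred, so only ratios
matter) and passed to the median-of-ratios estimator
(`spikeSizeFactors()`).  The resulting factors are proportional to each
sample's per-cell sequencing yield, so a global target-genome change
survives normalization — which is the entire point.

# The negative-binomial test

`nbWaldTest()` fits, per region, a log-linear negative-binomial model with
the log size factors as offset, by iteratively reweighted least squares at a
fixed per-region dispersion, and reports the Wald statistic of the requested
contrast against the normal reference with Benjamini–Hochberg adjustment.
Size factors are always supplied externally and never re-estimated from the
tested counts: with target-derived ("naive") factors the same machinery
reproduces the conventional analysis, which is useful as a negative control
but wrong for global changes.

Dispersions come from `momentDispersions()`: a method-of-moments estimate on
normalized counts using design-cell means with a residual-df correction,
shrunk toward a mean-dispersion trend (binned means of the raw estimates
along the normalized-mean axis) and floored at $10^{-8}$.  The shrinkage
weight (`priorDf`, default 20 pseudo-df against the region's `n - p`
residual df) was chosen for type-I calibration of the downstream Wald test
at small replicate numbers: with 3v3 designs the raw moment estimates are
too noisy to use unshrunk, and under null simulations the shrunk test holds
its nominal size (fraction of p < 0.05 within [0.03, 0.07], uniform
p-values) while remaining responsive to genuine dispersion trends.  This is
deliberately *not* a re-implementation of the empirical-Bayes machinery of
existing NB frameworks; the package's claim is statistical calibration, not
numerical equality with any of them.  Accordingly there is no independent
filtering and no fold-change shrinkage: the stated thresholds
(`callSignificant()`, padj < 0.05 and fold > 1.5, or fold > 2 for the
RING1B signal-loss peak filter) apply to maximum-likelihood estimates.

Separation (a design cell with all-zero counts) is handled by reporting the
fold change from 0.5-pseudocounted counts — fitting itself never sees
pseudocounts — and flagging the region.

`interactionTest()` fits `~ line * treatment` and reports the interaction
coefficient: whether the treatment effect differs between lines.  For the
partial-derepression question the package follows the union of two
complementary approaches (`classifyDerepression()`): a gene is "partially
derepressed" when the direct mutant-vs-knockout contrast in treated cells is
significantly down *or* the interaction term is significant with a smaller
treatment effect in the mutant line; genes flagged by neither are "fully"
derepressed.

# Gene classification

`classifyGenes()` reproduces the three-way promoter classification: promoter
windows are TSS ± 2500 bp per transcript; a gene with no promoter touching a
non-methylated island (NMI) is **Non-NMI**; otherwise it is **PcG** when its
promoters overlap both a RING1B and a SUZ12 peak set, else **Non-PcG**.  For
multi-transcript genes the default rule lets each feature be satisfied by
any promoter independently (the literal reading of "overlap of at least one
promoter with the feature of interest"); a stricter mode
(`samePromoter = TRUE`) requires one promoter to contact both peak sets.
The fixture generator plants split-promoter genes that distinguish the two
modes, and both are tested.  Overlap means >= 1 bp everywhere; no minimum
overlap fraction is imposed.

Peak sets are prepared by `filterPeaks()` (retain peaks reproduced in every
supplied set — both cell lines, or all biological replicates — then discard
blacklist overlaps; coordinates from the first-named set) and, for RING1B,
`filterBySignalLoss()` (keep peaks with padj < 0.05 and > 2-fold signal loss
in the knockout line, removing peaks whose apparent occupancy does not
depend on the factor).

# Capture-C quantification

`digestGenome()` cuts immediately before each exact occurrence of the
recognition motif (GATC for DpnII); fragment coordinates are bookkeeping
units, so the 5' overhang geometry of the real enzyme is deliberately
ignored and ambiguity codes never match.  Normalized counts are
`w / total_promoter_reads / n_promoters * 1e6`
(`normalizeCaptureCounts()`).  `mergeInteractions()` aggregates fragments
whose interaction score reaches 5 in *any* sample and merges runs whose
index distance is strictly less than 10 fragments; `quantifyPeaks()` then
averages normalized counts and scores over **all** fragments in each merged
span, including non-significant ones.  Merging is idempotent and independent
of input order, and these properties are tested on random instances.

# 3D Polycomb-body quantification

`segmentFoci()` processes each nucleus independently: per-slice rolling-ball
background subtraction (grayscale opening with a spherical-cap structuring
element, radius 4 px), Otsu thresholding of the voxels inside the nucleus
mask (256 histogram bins over the observed range), then 3D
connected-component labelling (26-connectivity by default, 6 available)
with components below 2 voxels discarded.  Outside-mask voxels are replaced
by the in-mask minimum before subtraction, making the result provably
mask-local.  `summarizeFoci()` reports per-nucleus counts, sizes,
intensities and the bright-focus count — the number of foci whose mean
intensity exceeds the 75th percentile of focus intensities pooled across
the whole dataset.  Whether that percentile should be taken per nucleus,
per condition or pooled is not standardized in the field; pooling across
the analyzed dataset is the default because it is the only choice that
makes "loss of bright foci in condition B" directly measurable, and the
other two are available via `pool=`.  Focus "intensity" defaults to the
mean (integrated intensity selectable).

# The synthetic-data generators

`simulateDualGenomeExperiment()` emulates dual-genome sequencing of mixed
cell populations.  Per sample: a mixing ratio (default 0.04 spike cells per
target cell, the ~1:25 mixing of calibrated ChIP protocols) with 10%
lognormal jitter; a sequencing depth drawn from `depthRange`; and region
weights equal to per-cell signal — target regions get lognormal strengths
multiplied by the depletion factor $\delta$ in treated, responsive regions,
spike regions get strengths scaled by the mixing ratio.  Counts are drawn by
a gamma-weight multinomial: weights receive Gamma noise with relative
variance `dispersion` and the configured depth is then distributed
multinomially, so sample totals are conserved *exactly* while region counts
are approximately negative-binomial.  This compositionality matters: when
$\delta$ shrinks the target signal, the spike read share rises, exactly as
in a real calibrated experiment — and it follows that spike-derived size
factors legitimately differ between treatment groups (they carry the global
loss), which is why the pipeline recovers $\delta$ while target-anchored
normalization reports no change.

Matched inputs share the sample's mixing ratio but none of its enrichment
structure (the spike/target split is a binomial draw at the cell-mixing
proportion), which is precisely why input ratios can correct the
calibration.  Defaults: 3v3 replicates, 2000 target and 500 spike regions,
depth 0.8–1.2 M reads, dispersion 0.05 — region-level counts in the
hundreds, the regime of the real peak/window quantitations.

`simulateExpression2x2()` generates the line-by-treatment expression design
with planted derepressed genes (default 4-fold) of which a subset responds
with a halved fold change in the second line; gDNA samples carry the mixing
information (default mixing 0.4, the RNA-style spike proportion).
`genAnnotationFixtures()` plants gene classes, NMIs, blacklist and
reproducible/private/blacklisted peak sets with a recorded truth table;
`simulateCaptureC()` plants contiguous high-score interaction spans on a
digested toy sequence with background scores strictly below the cutoff; and
`simulateImageStack()` places 3D Gaussian foci (rejection-sampled inside the
nucleus mask with a minimum separation of 8 voxels) on a flat background
with Poisson noise.

What the generators do *not* emulate: alignment artifacts, duplicate reads,
GC or mappability bias, fragment-length effects, spatially varying image
background, or overlapping/merging nuclei.  Passing tests therefore
demonstrate the correctness and statistical calibration of the analysis
logic under the stated model, not robustness to upstream artifacts, which
the real pipeline delegates to aligners, deduplication and peak callers.

# Numerical and design choices

* **Coordinates.**  In memory everything is 1-based closed `GRanges`, the
  Bioconductor convention; BED input/output converts at the file boundary
  via `rtracklayer`.  Promoter windows are `[TSS - hw, TSS + hw - 1]`
  (width `2 hw`), matching the half-open TSS ± 2500 bp window.
* **Untreated-median scaling.**  `normalizeSignal()` maps the untreated
  per-kb median to 2 so its log2 is 1; the constant is configurable and the
  transform invertible.
* **Percentile bins.**  Sites are ranked by expression with a deterministic
  index tie-break; a remainder of `n mod 100` is spread one site each over
  the leading bins (larger bins first), and bin 50 is the reference.
* **Counting rule.**  Any-overlap by default (each read increments every
  interval it touches, the behaviour of the standard multi-sample counting
  tools); midpoint assignment by option.  Strand is ignored for counting and
  used only to orient TSSs.
* **Calibration reference.**  Downsampling fractions are relative to the
  group minimum of $S$ — the only choice consistent with subsampling (all
  $f \le 1$); a designated reference sample can be named instead.
* **Merging distance.**  "Less than 10 fragments" is implemented strictly
  (`diff < maxGap` merges), and distance is the difference of fragment
  indices.
* **Dispersion floor** $10^{-8}$; all-zero regions are excluded from testing
  and reported as NA with padj propagating NAs.
* **Determinism.**  Every generator is a pure function of (config, seed);
  RNG state is restored afterwards.

# Worked example

A null and a global-depletion experiment, analyzed both ways:

```{r example}
cfg <- simConfig(seed = 11, depletionFactor = 0.2, fractionResponsive = 1)
sim <- simulateDualGenomeExperiment(cfg)

si <- sampleInfo(sim$counts)
chip <- si[si$role == "chip", ]
chip$condition <- factor(chip$condition, levels = c("UNT", "OHT"))

cal <- computeCalibration(sim$samples)
sfSpike <- spikeSizeFactors(spikeCounts(sim$counts)[, chip$sample_id],
                            cal$mixing_ratio)
resCal <- nbWaldTest(targetCounts(sim$counts)[, chip$sample_id], sfSpike,
                     chip, design = ~ condition, contrast = "conditionOHT")

sfNaive <- medianOfRatios(targetCounts(sim$counts)[, chip$sample_id])
resNaive <- nbWaldTest(targetCounts(sim$counts)[, chip$sample_id], sfNaive,
                       chip, design = ~ condition, contrast = "conditionOHT")

c(calibrated = median(resCal$log2FoldChange, na.rm = TRUE),
  naive = median(resNaive$log2FoldChange, na.rm = TRUE),
  truth = log2(0.2))
table(callSignificant(resCal))
```

The calibrated analysis reports the planted five-fold global loss
(median log2 fold change near `log2(0.2) = -2.32`, nearly all regions called
down); the naive analysis reports essentially nothing.

# Problem sizes used in validation

The packaged checks run the generators at the scale the statistics need and
no larger: differential validation at 3v3 replicates with 2000 target + 500
spike regions per experiment across four depletion factors and five null
seeds; classification recovery aggregated over three independent 2x2
experiments (260 genes each, 100 derepressed, 10 partial); merging
invariances over 100 random call sets; and foci recovery over 50 stacks of
128 x 128 x 20 voxels plus a 30-nuclei-per-condition bright-focus
comparison.

# Known limitations

* Dispersion estimation targets calibration, not efficiency: at very small
  replicate numbers the heavy trend shrinkage can under-react to genuinely
  outlying regions (no outlier refitting is attempted).
* The Wald normal reference is slightly anticonservative at 3v3; the null
  false-positive fraction sits near 0.055 rather than exactly 0.05.
* `quantifyPeaks()` treats fragments absent from the call table as zero
  counts, which is correct for complete per-fragment tables and
  conservative otherwise.
* The rolling-ball structuring element equates one pixel of radius with one
  intensity unit of ball height; for the high-contrast foci the pipeline
  targets, this is indistinguishable from a flat disc, and the flat-image
  and spike-preservation properties hold either way.
* Multi-nucleus masks are processed independently but foci are never split
  across nucleus boundaries; touching nuclei should be separated upstream.
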