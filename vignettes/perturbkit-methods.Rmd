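---
title: "Models and methods in perturbkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in perturbkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(perturbkit)
library(dplyr)
```

perturbkit analyses pooled CRISPR interference (CRISPRi) perturbation
experiments in cultured tumour cells across three readouts: bulk dual-sgRNA
screens read out by sgRNA counting, Perturb-seq (single-cell RNA with guide
capture), and single-nuclei multiome data that couples ATAC, RNA and guide
capture in the same nuclei. This vignette explains the models behind each
stage, the tunable parameters and their defaults, what the synthetic-data
generators do and do not emulate, and the numerical conventions the
implementation commits to.

## Screen phenotypes and hit calling

A dual-sgRNA vector's **growth phenotype (gamma)** is the log2 ratio of its
endpoint (T12) to initial (T0) library-normalised counts, centred on the
median of the non-targeting control (NTC) vectors, per replicate. The
**radiation phenotype (rho)** is the log2 ratio of endpoint counts in the
radiotherapy arm to endpoint counts in the untreated arm. Centring on the
NTC median removes the arbitrary scale left by library-size normalisation;
after `compute_phenotypes()` the NTC medians of both phenotypes are zero by
construction (to floating-point resolution when the NTC count is even).

Design choices that the definitions above leave open, and how this package
resolves them:

* **Rho centring.** The rho ratio compares two T12 populations, so its raw
  value already cancels most scale effects, but hit calling uses a
  *normalised* phenotype; we therefore centre rho on the NTC median and
  scale it by the robust SD of NTC pseudo-genes exactly as for gamma. The
  centring can be disabled (`center_rho = FALSE`).
* **Population doublings.** Phenotypes are reported per the log2-ratio
  formula without dividing by the number of population doublings; the two
  arms in this assay differ in doubling count, so per-doubling scaling would
  change the relative magnitudes of gamma and rho. Users who want
  per-doubling units can divide the returned columns themselves.
* **Vector-level significance** is a two-sided Welch t-test on log2
  library-normalised counts across replicates (raw scale available via
  `log_scale = FALSE`). Degenerate inputs follow a deterministic convention:
  equal replicate values on both sides give p = 1; unequal means with zero
  variance get a variance floor of 1e-8 so the test is defined and very
  small.
* **Gene-level significance.** Per replicate, the gene value is the mean of
  its vectors' NTC-centred log ratios; the gene p-value is a two-sided
  one-sample t-test of the replicate values against zero. This matches a
  design with a handful of replicates and avoids pooling vectors with
  heterogeneous efficacies into one test.
* **Pseudocount.** One normalised count unit is added before every log
  ratio. Vectors passing the 100-read T0 filter are essentially unchanged by
  it; it only prevents infinite ratios for dropout vectors.

Hit calling uses the **discriminant score** `|z| * (-log10 p)` where `z` is
the gene phenotype divided by the robust SD (MAD) of NTC *pseudo-genes* —
NTC vectors partitioned into groups of the same size as a real gene's vector
set (default: the median vectors-per-gene in the library; remainder NTCs are
dropped) and scored identically to genes. A gene is a hit when the
discriminant reaches the threshold (default 5, boundary inclusive). The
**empiric FDR** at a threshold is `(pseudo-gene pass rate x number of
genes) / number of gene hits`; this is a documented convention built on the
standard NTC-pseudo-gene idea, not a claim of equivalence to any particular
published pipeline's estimator. `call_hits()` also reports the smallest
threshold achieving a target FDR.

`clopper_pearson()` provides the exact binomial confidence interval used for
reporting classification or assignment accuracies; for 15/15 successes the
95% lower bound is `100 * 0.025^(1/15)` = 78.2%.

```{r screen-example}
cfg <- sim_config(n_genes = 200, n_ntc = 40,
                  rho_effects = c(G0001 = -1.5, G0002 = 1),
                  seed = 7)
sim <- simulate_screen(cfg)
hits <- sim$counts |>
  filter_screen_counts(sim$library) |>
  normalize_library_size() |>
  compute_phenotypes(sim$library) |>
  gene_level_scores(sim$library) |>
  call_hits("rho", threshold = 5)
glance(hits)
```

## Perturb-seq

Cells are retained when they have strictly more than 200 detected genes and
UMIs for exactly one guide (`assign_single_guide()`). Knockdown is the
pseudobulk ratio `(on-target + 0.01) / (NTC + 0.01)` on per-cell normalised
expression, computed within a GEM lane so lane-specific ambient RNA and
depth do not bias the ratio. Per-cell normalisation targets 10,000 counts;
because every downstream quantity is a ratio of pseudobulks on the same
scale, the constant is immaterial and recorded only for reproducibility.

Retention of perturbations requires knockdown strictly greater than 75% in
at least one untreated lane and at least 10 cells in every condition, both
read literally from their wording (strict and inclusive respectively).

Module scores compare the mean pseudobulk expression of a module's top
markers for a perturbation in a condition against NTC cells at 0Gy, log2
transformed with the same 0.01 pseudocount as knockdown. The reference
column is exactly zero, which the tests assert. Marker selection requires
detection in at least 25% of in-cluster cells and a mean fold change above
25% versus all other cells; the fold-change gate is applied as
`log2 FC > log2(1.25)` and "most specific" is ranked by descending fold
change with ties broken by detection-rate difference, then gene id.

Differential expression uses a two-part hurdle-style test: a Fisher exact
test on the 2x2 detection table combined, via Fisher's method, with a
Wilcoxon rank-sum test on normalised expression in cells where the gene is
detected. A plain rank-sum test over all cells is available
(`method = "wilcox"`). This is a documented, testable stand-in for
hurdle-model packages used in this field; no result in this package depends
on matching any specific package's p-values. A gene is differentially
expressed when `p < 0.05` and `|log2 FC| > 1`, both strict. A perturbation
is flagged radiotherapy-selective when its excess DEG count (fractionated
radiotherapy minus untreated) is strictly greater than 40; the inclusive
variant of that rule is available via `rule = "at-least"`.

Two deliberate resolutions of ambiguities: pseudobulk means are computed on
per-cell normalised values and then averaged (matching the stated order of
operations), and the two untreated lanes are pooled for DE while knockdown
stays within-lane.

## Single-nuclei multiome

**Guide assignment** follows the hypergeometric scheme: per cell, guides
with fewer than 6 UMIs are dropped; each surviving guide is tested for
enrichment against the dataset-wide guide UMI pool with an upper-tail
hypergeometric probability; BH correction is applied across the cell's
surviving guides; the majority guide is assigned iff adjusted p < 0.05, the
log2-odds ratio between the two highest counts exceeds 1, and total
surviving UMIs exceed 6. The per-guide filter precedes the total-UMI gate,
matching the stated order. The log-odds ratio uses a pseudocount of 1 on
both counts so a zero second count is defined; ties give LOR = 0 and are
never assigned.

**QC metrics.** ATAC UMI counts unique fragment records per barcode; the
nucleosome signal is mono-nucleosomal (147-294 bp, inclusive) over
nucleosome-free (<147 bp) fragments, with longer fragments ignored by the
ratio; zero nucleosome-free fragments give an infinite signal, which fails
the filter. TSS enrichment averages strand-oriented per-base coverage over
TSSs in a +/-1000 bp window and divides the central +/-50 bp by the mean of
the two outer 100 bp flanks — one of several conventions in circulation,
documented here. The retention bounds (ATAC UMI in (1000, 100000), RNA UMI
in (50, 25000), nucleosome signal < 4, TSS enrichment > 1) are read as open
intervals, and undefined metrics fail.

**Gene activity** counts fragments overlapping the 2000 bp upstream of each
TSS (half-open windows, any shared base counts); the implementation is
checked exactly against an all-pairs interval oracle. Differential module
activity subtracts log2 pseudobulk activity (pseudocount 0.01) in the
untreated condition from the radiotherapy condition, pooling a target's two
guides.

**Motif deviations** re-implement the published bias-corrected deviation
idea: expected counts proportional to each peak set's share of the dataset
total, raw deviation `(observed - expected) / expected`, and z-scores
against 50 background peak sets matched on deciles of GC content and log
mean accessibility (sampling with replacement; seed recorded in the
output). A motif whose raw deviations are exactly zero for every cell — the
all-peaks motif being the canonical case — gets z defined as zero, since
there is no signal to calibrate. On null simulations the pooled z-scores
have mean within 0.05 of zero and SD within 0.1 of one, which the tests
assert. Differential deviations keep motifs whose cognate TF is detected in
at least 5% of cells (no threshold is stated anywhere authoritative; 5% is
a conventional detection floor) and subtract mean z-scores directly —
log-transforming signed z-scores is ill-defined, so the signed difference
is the default and `legacy_log2 = TRUE` applies `sign(x) * log2(1 + |x|)`
first for users who want a compressed scale.

**Differential accessibility** predicts group membership from binarised
peak accessibility plus a `log1p(total)` depth covariate in a logistic
regression, tested against the covariate-only null with a 1-df
likelihood-ratio test; fold changes are detection-rate ratios with a
pseudocount, and BH-adjusted p-values are reported. **Average profiles**
accumulate duplicate-weighted per-base coverage over +/-1000 bp around
region centres and normalise by the mean of the two 100 bp end flanks, so
constant coverage maps to a profile identically 1.

## What the simulators emulate

The generators produce data with the statistical structure the analyses
assume, plus ground truth for parameter-recovery tests:

* **Counts** are negative binomial in a mean/overdispersion
  parameterisation (`variance = mu + phi mu^2`). No count model is imposed
  by the assay itself; NB is the field-standard overdispersed choice. Bulk
  screen reads use `phi = 0.05` (sequencing of amplified cassettes is far
  less dispersed than single-cell UMIs, which default to `phi = 0.5`).
* **Screens**: T0 at 500x coverage per construct in triplicate; T12 scales
  abundance by `2^gamma` (untreated) and additionally `2^rho`
  (radiotherapy), with independent per-replicate log2 noise of SD 0.15 — a
  free parameter, since nothing constrains between-replicate variance;
  0.15 gives replicate correlations comparable to well-executed screens.
  Configurable fractions of vectors carry discordant target labels
  (recombination) or low T0 depth to exercise the filters.
* **Perturb-seq**: integration counts are zero-truncated Poisson at MOI 0.1
  (cells are sorted for transduction, so observed cells have at least one
  integration); capture UMIs concentrate on the true guide(s) with optional
  ambient background proportional to guide abundance — the same
  population-frequency null the hypergeometric assignment assumes; target
  genes are scaled by `1 - knockdown` and module genes by per-condition
  shifts; lanes mirror the two-untreated-lanes design.
* **Multiome**: fragment lengths are a two-component mixture
  (nucleosome-free around 75 bp, mono-nucleosomal around 200 bp); per-cell
  depths span the QC bounds so filters are exercised; promoter fragment
  rates carry the programmed module activity shift; peak counts carry motif
  effects in the perturbed-radiotherapy stratum. Peak and RNA matrices are
  simulated at matrix level with the same NB model rather than re-derived
  from the fragment records — they feed the deviation and DA operations
  directly, and nothing downstream requires the two layers to be coupled.

They deliberately do **not** emulate: read-level sequence (no FASTQ),
alignment artefacts, doublets beyond multi-integration, batch effects
between lanes, cell-cycle structure, or realistic gene-gene correlation.
Passing recovery tests therefore demonstrates that the estimators invert
the generative model they assume, not that they are robust to every
artefact of real data.

One interaction worth knowing about: per-cell normalisation is
compositional, so a programmed effect on a gene (or module) that is a large
share of the simulated transcriptome is attenuated in normalised units.
Recovery tests therefore simulate transcriptomes of a few hundred genes so
programmed effects pass through with attenuation well below the test
tolerances — real transcriptomes are far larger and the effect smaller
still.

## Problem sizes and numerical conventions

The test suite and the acceptance script use: screens of 1,000 genes + 100
NTC vectors in triplicate (20 seeds for effect recovery); Perturb-seq
datasets of ~4,000 cells across four lanes (≥200 cells per guide and lane
for knockdown recovery); multiome datasets of 200 cells, 300 peaks and 5
motifs with 50 background sets. These sizes make every recovery estimate
comfortably tighter than its stated tolerance while the whole suite runs in
about a minute.

Other conventions: all genomic coordinates are 0-based half-open
internally, with conversions only at parse/emit boundaries (BED is native;
GTF is shifted on read); tie-stable orderings are by (score, id);
hierarchical clustering of score matrices uses complete linkage on
1 - Pearson correlation and falls back to input order for degenerate
matrices (fewer than three rows, or zero-variance rows); and every
simulator derives per-component seeds deterministically from one global
seed, so identical configurations reproduce byte-identical outputs.

## Known limitations

* The empiric-FDR construction and the gene-level p-value aggregation are
  documented conventions; other reasonable choices exist and would give
  slightly different hit lists near the threshold.
* The hurdle-style DE test is not a drop-in replacement for mixed-model
  hurdle packages; its detection component dominates for sparsely detected
  genes.
* The motif-deviation z-scores reproduce the published algorithm's
  definition, not any specific implementation's numerics (binning and
  background sampling differ in detail).
* TSS enrichment follows one documented flank convention; absolute values
  are not comparable across tools, only the >1 retention rule is.
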