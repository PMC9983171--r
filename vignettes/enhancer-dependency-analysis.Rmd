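---
title: "Enhancer dynamics, MLL3/4 dependency and transcriptional coupling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Enhancer dynamics, MLL3/4 dependency and transcriptional coupling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(enhancerdyn)
library(dplyr)
```

## Overview

`enhancerdyn` analyses how enhancer chromatin marks change during the
naive-to-formative transition of pluripotent stem cells, how those
changes depend on the MLL3/4 (KMT2C/D) methyltransferases, and whether
they are coupled to the transcription of nearby genes. The pipeline runs
from CPM-scaled signal tracks (bedGraph) and per-feature count matrices
to per-peak category tables, enhancer–gene linkage statistics and a
chromatin-state segmentation. A first-class synthetic-data generator
plants every structure the pipeline is meant to detect, so each stage is
testable with known answers.

This vignette documents the models, the tunable parameters, the
numerical choices, and what the synthetic experiments do and do not
demonstrate.

## Peak calling

CUT&RUN/CUT&TAG tracks are sparse: most of the genome carries no signal.
The caller therefore works on *blocks* — maximal runs of strictly
positive signal — scored by their total area (AUC, the sum of value
times width). In control mode a target block is kept when its AUC
strictly exceeds the empirical `1 - alpha` quantile (type-7
interpolation) of the IgG control's block AUCs; `alpha` defaults to
0.05. A top-fraction mode keeps the top fraction of blocks by AUC when
no usable control exists. Two deliberate choices:

* ties at the threshold are excluded (strict `>`), making the called set
  deterministic and the quantile rule exactly testable;
* blocks separated by even a single zero base are never merged; the
  union-peak step downstream merges overlapping or bookended peaks
  across samples instead.

Calling is invariant to a common rescaling of target and control, so it
does not matter whether tracks are CPM-scaled per sample or depth
matched — as long as target and control share a scale. The simulated IgG
control is emitted on the mark tracks' per-read scale for this reason;
with a real IgG library sequenced to comparable depth, per-sample CPM
achieves the same thing.

## Differential quantification

Counts are quantified over the union of called peaks (or directly over
features), filtered at CPM > 1 in at least two samples, and normalised
with TMM (trimmed mean of M-values: 30 % log-ratio trim, 5 %
absolute-intensity trim, precision weights, reference sample chosen by
upper quartile). Library sizes are fixed at the pre-filter column sums
so filtering cannot change the CPM scale.

The differential test is a per-feature negative-binomial Wald test:
log fold changes are ratios of TMM-normalised group means with
pseudocount 0.5 (bounded log2FC at zero counts), and the Wald variance
uses a method-of-moments dispersion shrunk toward a trend fitted on
binned means (prior weight 10 pseudo-degrees of freedom). Because the
per-feature dispersion at two or three replicates is extremely noisy,
p-values are referred to a t distribution with residual-plus-prior
degrees of freedom rather than a normal; this keeps the null
calibration conservative (the acceptance script measures the fraction
of BH-significant features on a fully null simulation). A
label-permutation alternative compares each feature's |log2FC| with its
group-relabelling null — all distinct assignments when there are at
most 1000, otherwise 1000 sampled under a seed. Note the resolution
limit of an exact permutation p-value: with two groups of *n* samples
the smallest achievable p is `2 / choose(2n, n)`, so BH significance at
0.05 requires roughly six replicates per group; the NB Wald test is the
default for small designs.

## Classification

The category logic is the package's core. Thresholds are collected in
`enh_thresholds()` and every cutoff is exposed:

| parameter | default | meaning |
|---|---|---|
| `fdr_dyn`, `lfc_dyn` | 0.05, 1 | dynamic (naive/formative) peak calls |
| `fdr_shared`, `lfc_shared` | 0.1, 0.7 | confident "no change" (shared) calls |
| `dep_lfc` | −1 | DKO/WT log2FC below which a site is dependent |
| `indep_lfc` | −0.7 | DKO/WT log2FC above which (in both states) a site is independent |
| `overlap_frac` | 0.75 | fraction of an ATAC peak that must be covered |
| `promoter_window_bp` | 1000 | TSS window for the Promoter class |

Peaks falling between the dynamic and shared rules (e.g. FDR 0.07 with
a large fold change) are `unclassified` rather than forced into a
category; sites between −1 and −0.7 are `intermediate`. Dependency is
evaluated per state and a site is dependent when *either* state drops
below the cutoff. The dynamic-peak FDR appears in the source material
as both 0.01 and 0.05; the default here is 0.05 and the parameter is
exposed. Similarly, the published description of the independent rule
is internally inconsistent in the running text; the figure-legend form
(both states above −0.7) is implemented.

Dependency fold changes are computed on the log2 scale of
TMM-normalised mean counts. The per-bp Log2CPM *density*
(`log2(CPM + 1) / width`) is implemented literally as stated — constant
1e6 applied to the scaled counts, plus one, log2, divided by width — and
used where a width-normalised abundance is wanted; the ±1/±0.7
dependency cutoffs are only dimensionally meaningful on the
log-fold-change scale, which is what the pipeline feeds them.

Feature classes are assigned by peak midpoint: Promoter within ±1 kb of
a TSS (the window is a package choice — annotation tools differ and no
window is canonical), Distal when intergenic (or intronic when exon
structure is supplied), Other for remaining gene-body overlaps. With
BED6-only gene models introns are not resolvable, so non-promoter
gene-body midpoints fall in Other; this fallback is a documented
approximation, not a claim about any reference tool's behaviour.

Joint H3K4me1-by-H3K27ac categories use any-overlap (≥ 1 bp)
co-location; when several H3K27ac peaks overlap one H3K4me1 peak the
largest overlap wins, and an overlapping but not-significantly-changing
H3K27ac peak counts as `maintain`.

## Linkage and coupling statistics

Each peak is linked to the gene with the nearest TSS (by peak midpoint;
ties go to the lower TSS coordinate, then lexicographic gene id, so the
assignment is deterministic). Per-category expression tests use the
paired Wilcoxon signed-rank across sample classes on per-gene log2 CPM
(replicate-averaged, then `log2(x + 1)`), genes deduplicated so a gene
linked by several peaks counts once; the published legends say "paired
rank-sum", a common conflation — signed-rank is the paired test, and an
unpaired flag is provided. Exact null distributions are used for n ≤ 25,
the normal approximation with continuity correction above. All
p-values within a testing family are Benjamini–Hochberg corrected.

The Monte-Carlo control test asks whether a state's nearest genes
differ in location from the all-genes pool: the observed Mann–Whitney U
compares the gene set against the pool, and the null is built from
same-size subsets drawn from the pool without replacement (exhaustive
enumeration whenever the number of subsets fits within `n_perm`,
default 1000 — the number of draws is a package choice). The two-sided
empirical p is the fraction of draws whose U deviates from the null
centre at least as much as the observed one; on the 4-value toy pool
with a 2-gene state set this reproduces the complete-enumeration answer
of 2/6 exactly.

Enhancer-burden effects are estimated two ways: an identity-link
Gaussian GLM (OLS) of per-gene expression log2FC on the count of
dependent enhancers, with a 95 % CI on the slope; and bins of the
percentage of a gene's enhancers that are dependent
({0, (0,25], (25,50], (50,75], (75,100]} %), each bin compared with the
0 % bin by unpaired Wilcoxon. Genes with no linked enhancer are
excluded from both — an explicit package choice, since the published
analyses do not state how such genes enter.

## Chromatin states

Four tracks (H3K4me1 and H3K27ac in WT and DKO, one condition at a
time — conditions are segmented separately) are binned at 200 bp
(ChromHMM's default width; configurable) and binarized by a Poisson
upper-tail test at `pcut = 1e-4` against the genome-wide mean rate.
Bin signal is converted to read-equivalent counts in units of the
smallest positive track value (one fragment, for linearly scaled
tracks). With four binary tracks the saturated model has 16 states, so
the default segmentation is the direct combinatorial encoding — state
id 1 plus the binary number formed by the track vector, first track
most significant. A Bernoulli-emission HMM (Baum-Welch; log-domain
forward–backward and Viterbi implemented in C++) is provided for
noisier data; emissions are initialised from per-state perturbed
empirical track frequencies under a seed, transitions diagonal-heavy,
emission probabilities clamped to [1e-4, 1 − 1e-4], and training stops
at relative log-likelihood tolerance 1e-4 or 200 iterations. The
forward and backward passes agree to numerical precision and the
likelihood is non-decreasing across EM iterations; both properties are
asserted in the tests rather than assumed.

Per-state expression testing mirrors the published analysis: state
intervals are kept when they cover ≥ 75 % of a WT ATAC peak, restricted
to Distal, linked to nearest TSSs, and each state's gene set is tested
against the all-genes control with the permutation test; states whose
emission pattern carries no mark at all are excluded.

## The synthetic generator

`sim_config()` defines the reference experiment: 2 chromosomes × 5 Mb,
2,000 planted 1-kb enhancers (bin-aligned, ≥ 200 bp apart), 1,000 genes,
two conditions × two genotypes × two replicates. Defaults were fixed
once, on these grounds:

* **Dynamics proportions** 0.11/0.11/0.78 (naive/formative/shared) —
  the approximate composition of the real landscape, where shared peaks
  outnumber each dynamic class by roughly seven to one.
* **Dependency proportions** per mark (H3K4me1: 1/1/0.15 for
  naive/formative/shared; H3K27ac: 0.57/0.62/0.22) — dynamic H3K4me1 is
  fully MLL3/4-dependent while most shared H3K4me1 and a more mixed
  share of H3K27ac is not, which is the biology the pipeline must
  resolve.
* **Effect sizes** — planted dynamics log2FC 2 and dependency log2FC −2
  (the magnitude the dependent/independent cutoffs are designed
  around); peak enrichment 2^8 over a background of 0.0004 reads/bp.
  CUT&RUN-class assays have very high signal-to-background, and on a
  desk-scale genome the enrichment must simultaneously keep background
  blocks sparse (for AUC calling) and peak bins well above the Poisson
  binarization threshold.
* **Noise** — NB dispersion 0.02 for fragment counts (isogenic
  cell-line replicates are tight), 0.05 for expression; per-gene
  genotype log2FC noise SD 0.25.
* **Coupling** κ ∈ [0, 1] scales how much of a gene's DKO/WT expression
  log2FC is explained by the mean planted acetylation log2FC of its
  coupled enhancers. The default is κ = 0 — the decoupled regime is
  the observation the generator exists to emulate — and the coupled
  regime κ = 1 is exercised alongside it in tests and in the
  acceptance script.

Expected counts are `depth × width × 2^enrichment / W` against a fixed
all-sites reference weight `W`, so planted fold changes are exact on
the raw count scale; sample classes that lose signal (DKO at dependent
sites) then have genuinely smaller in-peak library sizes, which TMM
corrects downstream — the generator does not pre-normalise away the
compositional shift the pipeline is supposed to handle.

Truth linkage is nearest-TSS by construction (computed by exhaustive
search, independently of the linkage module's sorted-search
implementation), so linkage output can be compared with truth exactly.

**What the generator does not emulate:** read-level artifacts
(duplicates, mappability, GC), fragment-length structure, spike-in
calibration, batch effects, diploid genomes, distance-dependent
enhancer–promoter interaction, or indirect/trans effects of MLL3/4
loss. Passing recovery tests on synthetic data therefore demonstrates
that the statistical machinery is correct and well calibrated under the
planted model — not that the thresholds would reproduce any particular
real-data peak count.

## Problem sizes and determinism

The reference analyses run at the default scale above (a full
simulate–call–test–classify–link–segment pass takes well under a minute
on one CPU; the HMM recovery experiment uses a 50,000-bin chain).
Every stochastic step takes a seed — the generator threads small fixed
offsets from `sim_config(seed)` through its stages, permutation and HMM
functions take explicit `seed` arguments — and repeated runs are
byte-identical, which the test suite asserts on written files.

## Known limitations

* The NB Wald test is moderated but not a full empirical-Bayes
  treatment; with two replicates per group its shared-peak calls lean
  on the BH behaviour of the whole peak set (a small fraction of truly
  unchanged peaks land in `unclassified` rather than `shared`).
* The exact permutation test's p-value floor makes it unsuitable for
  BH-corrected discovery at small replicate numbers (see above).
* The combinatorial segmentation is exact for saturated designs but
  offers no smoothing; the HMM path trades exactness for robustness on
  noisy tracks.
* With BED6-only gene models, intronic peaks are indistinguishable from
  exonic ones and fall into Other.
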