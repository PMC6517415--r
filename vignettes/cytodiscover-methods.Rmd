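---
title: "Methods: high-resolution clustering and moderated differential tests for cytometry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: high-resolution clustering and moderated differential tests for cytometry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

High-dimensional flow and mass cytometry measure tens of protein markers in
hundreds of thousands of single cells per sample. Two differential questions
dominate multi-sample comparisons: *differential abundance* (DA) — does the
relative frequency of a cell population differ between conditions? — and
*differential states* (DS) — does the expression of a functional (signaling)
marker change within a population? cytodiscover answers both by summarizing
cells into a large number of small clusters and testing cluster-level
features with moderated and mixed-model statistics borrowed from
transcriptomics, where small-sample count testing is a mature art.

The design rests on two ideas:

1. **High-resolution, merge-free clustering.** Cells are clustered on *cell
   type* markers only, into 100–400 self-organizing-map (SOM) nodes. No
   meta-clustering is applied: merging nodes risks absorbing a rare
   population (0.1–5% of cells) into a large neighbor, exactly the signal a
   DA analysis is after. Interpretation happens after testing, via heatmaps.
2. **Information sharing across clusters.** With 5–16 samples, per-cluster
   variance estimates are noisy. The count-based DA test shares a common
   negative binomial dispersion across clusters; the linear-model routes
   squeeze per-cluster variances toward an empirical Bayes prior (optionally
   a mean–variance trend). Mixed-model routes instead absorb overdispersion
   with observation-level random effects (OLRE).

## Preprocessing

Raw intensities are approximately log-normal with zeros and small negatives
from instrument background subtraction. All analysis happens on
`asinh(x / cofactor)` — log-like for large values, linear and odd-symmetric
near zero. The cofactor (default 5 for mass cytometry, 150 for flow) sets
the width of the linear region. Equal-size subsampling is available but off
by default: discarding cells costs most exactly where power is scarcest, in
rare populations.

## Clustering

`som_train()` runs an online SOM on the arcsinh scale with no variable
rescaling (the transform already stabilizes scale, and rescaling inflates
noise-only markers). Per presented cell, the best-matching unit (BMU;
Euclidean distance, ties to the lowest node index) and all nodes within the
current grid radius move toward the cell by the current learning rate. The
defaults are a 10 x 10 planar grid (100 clusters; up to 40 x 40 for
resolution sweeps), 10 passes through the data, learning rate decaying
linearly 0.05 to 0.01, and a rectangular ("bubble") neighborhood whose
radius decays linearly from half the grid diagonal to 0, so training ends
with pure BMU refinement. Initialization draws codebook vectors from K
random cells; presentation order is reshuffled each pass. Everything is
deterministic given the seed, which is drawn from a named substream so that
e.g. toggling subsampling does not perturb the SOM. These schedule choices
are package defaults in the spirit of the reference SOM implementations;
they are all exposed in `som_params()` because no single convention is
canonical.

The number of clusters is *the* user parameter. Too few clusters merge
populations (rare spikes disappear below the >50% purity level); too many
spread counts thin and pay a larger multiple-testing price. The package's
own sweep (see `scripts/acceptance.R`) shows the rare-spike benchmark's
partial AUC dropping when 9 clusters replace 100.

## Cluster features

`compute_counts()` tallies a K x S cluster-by-sample count matrix (the
per-sample totals are the "library sizes" of the count models);
`compute_medians()` stores the median arcsinh expression per
cluster–sample–marker, with the even-count convention (mean of the two
middle order statistics) and `NA` where a cluster has no cells in a sample.
Clusters with fewer than `min_cells = 3` cells in at least
`min_samples = floor(S/2)` samples are filtered before testing — the
thresholds are deliberately permissive so rare populations survive, and are
exposed in `filter_rule()`.

## Designs and contrasts

Designs are one row per sample with treatment coding and an explicit
intercept (reference = first observed level; columns ordered intercept,
group, block, batch, covariates). Contrasts are written against named
columns, so they are robust to coding details. Every test reduces to the
same null by rotating the design so the (normalized) contrast becomes the
last coefficient; count LRTs drop that column for the null fit, and linear
and Wald tests test it directly. Paired designs can put the block either in
the design (fixed) or, in the mixed/consensus-correlation routes, as a
random intercept.

## The five tests

* **`run_da_nb`** — NB GLMs on cluster counts with log effective-library
  offsets; one common dispersion maximizes the summed Cox–Reid adjusted
  profile likelihood (1-D search over log dispersion in [1e-6, 10], the
  inner IRLS being an ordinary GLM fit at fixed dispersion); per-cluster
  likelihood-ratio tests against chi-squared(1). Common (not tagwise or
  trended) dispersion with LRT is the deliberate scope; quasi-likelihood F
  tests are not provided.
* **`run_da_wlm`** (`run_da_weighted_lm`) — log2-CPM counts
  (`log2((c + 0.5)/(n + 1) * 1e6)`) with mean–variance precision weights: a
  LOWESS curve (span 0.5) of sqrt residual SD against average log2 count
  from per-cluster linear fits, mapped to each observation's fitted
  log-count (linear interpolation, constant extrapolation) and raised to
  the −4th power. Weighted least squares, variance squeezing with a
  constant prior, moderated t.
* **`run_da_glmm`** — one binomial GLMM per cluster (counts out of
  per-sample totals, logit link) with a per-sample OLRE absorbing
  extra-binomial overdispersion and optionally a block random intercept.
  Fitting is Laplace-approximated maximum likelihood: a penalized IRLS
  inner loop for the joint fixed/random mode, an outer direct search over
  log random-effect SDs. The default test is Wald z; under complete
  separation (a spiked population entirely absent from one condition) the
  Wald statistic collapses (Hauck–Donner), so a likelihood-ratio option is
  provided — the LRT stays informative because the likelihood has a finite
  separation limit. The adaptive Gauss–Hermite oracle for this fitter lives
  in the test suite, not the package.
* **`run_ds_moderated`** — per cluster x state-marker medians, weighted
  least squares with the cluster–sample cell counts (normalized to mean 1)
  as precision weights, variance squeezing *with* a trend on average median
  expression, moderated t, and BH across all cluster–marker combinations
  jointly.
* **`run_ds_lmm`** — one linear mixed model per cluster–marker combination
  (REML via lme4/lmerTest), block random intercepts for paired designs,
  per-sample weights proportional to cells per sample (a per-combination
  model cannot see between-cluster count variability, so only sample totals
  are weighted). The contrast is tested with a t statistic on Satterthwaite
  denominator degrees of freedom: a plain Wald z reference is visibly
  anti-conservative at 8 vs 8 (and worse below), enough to fail
  null-calibration checks, whereas the Satterthwaite t is the field's
  standard small-sample correction. With no random terms the route
  collapses to an ordinary weighted linear model with a t test.

For random-effect paired designs in the linear routes, a consensus
within-block correlation is estimated by per-unit REML profiling of a
one-random-intercept model, combined by a 15% trimmed mean on the Fisher z
scale, and applied through generalized least squares with a
block-exchangeable correlation. All-singleton blocks are rejected (use
fixed-effect blocks).

Missing medians drop that sample from that combination's fit; if that
leaves a fixed-effect column aliased (e.g. both samples of a block gone),
the column is dropped provided the contrast does not load on it, otherwise
the unit is reported with a missing p-value. Units with no residual degrees
of freedom are excluded from squeezing. Benjamini–Hochberg adjustment is
applied across retained clusters (DA) or all retained cluster–marker
combinations jointly (DS); missing p-values stay missing.

## The synthetic benchmark generator

The published benchmarks of this problem class splice real FCS files with
spiked-in cells; those data are external, so the package ships a parametric
generator that emulates their statistical structure and serves as the study
condition for all tests. One seed draws:

* 8 base cell populations as Gaussians on the arcsinh scale, means uniform
  on [0, 4] over 10 cell type + 4 cell state markers, within-population SD
  0.35, mixing proportions Dirichlet(5);
* paired two-condition samples (5 vs 5 for DA, 8 vs 8 for DS, 5000 cells
  each by default): each block (patient) shares a per-marker mean offset
  (SD 0.1) and a log-proportion offset (SD 0.15) between its two samples,
  and each sample adds its own log-proportion noise (SD 0.10) — the mild
  extra-multinomial overdispersion that motivates OLRE terms;
* a spiked DA population with a mean vector at least Euclidean distance 2
  (over type markers) from every base population, replacing exactly
  `round(threshold x cells)` cells in each condition-2 sample at thresholds
  5%, 1% or 0.1%; `signal_strength` scales this phenotype toward its
  nearest base population (0.25 mimics a 75% signal reduction);
* a DS shift of `state_shift = 1.5` arcsinh units on the first state
  marker of the most abundant population, condition-2 samples only — type
  markers are untouched, so the clustering is provably condition-blind (the
  generator's type-marker values are bit-identical to its matched null);
* matched nulls (no spike, no shift) with exchangeable group labels.

Values are stored on the raw scale through the inverse transform, so every
analysis exercises the full pipeline including the arcsinh step. The
nuisance parameters above are the package's own choices of "realistic"
(they produce per-cluster count dispersions around 0.01–0.05 and
between-sample median SDs of a few hundredths, in the range seen in real
cohorts); they are config-exposed but the defaults define the reference
conditions. What passing tests on this generator does *not* show: behavior
under heavy-tailed or multimodal marker distributions, batch-structured
acquisitions, or spike phenotypes that overlap their background — the
generator's populations are cleaner than real data, which is exactly why
the evaluation also reports null calibration, not only power.

## Evaluation

A cluster is labeled truly differential when strictly more than half of its
cells are spiked (for DS: belong to the target population). Metrics are ROC
curves with tie grouping, partial AUC over FPR < 0.2 normalized to [0, 1],
TPR and observed FDR at adjusted-p cutoffs {0.01, 0.05, 0.1} (0/0 = 0), and
a one-sample Kolmogorov–Smirnov uniformity check for null p-values. Missing
p-values rank worst and never count as detected. Evaluation is available at
cluster level (the >50% rule) and at cell level, where each cell inherits
its cluster's score — the cell level matches how the original benchmark
figures weight performance and prevents tiny spike fragments (a handful of
filtered cells with >50% purity) from dominating TPR.

## Numerical choices and degenerate inputs

* IRLS: tolerance 1e-8, 100 iterations (GLM); penalized IRLS 1e-6, 50
  iterations (GLMM), outer variance search over log SD in [-6, 3].
* Dispersion search: 1-D on log scale, tolerance 1e-6; clusters whose GLM
  fails to converge are dropped from the profile sum.
* LOWESS span 0.5 everywhere a trend is fitted; interpolation is linear
  with constant extrapolation.
* Variance squeezing solves the trigamma moment equation by Newton
  inversion; fewer than 3 units fall back to an infinite prior with a
  warning; zero variances are floored at 1e-12 before logging.
* Ties in BMU assignment go to the lowest node index; empty SOM nodes are
  retained as all-zero count rows.
* TMM factors are renormalized to geometric mean 1; an all-zero sample is
  an error. Effective library sizes enter the NB offsets and log-CPM
  directly and are rounded to integers as GLMM binomial totals (the one
  place a continuous total is not meaningful).
* A constant DS response returns effect 0 with p = 1 by convention;
  complete GLMM separation keeps the (large) estimate and reports a
  missing Wald p.

## Problem sizes used in the shipped checks

The test suite and `scripts/acceptance.R` run the study conditions at 2000
cells per sample for the ten null-calibration replicates (8 vs 8, 100
clusters), 5000 cells per sample for the power benchmarks (5 vs 5 with 400
clusters for DA at 5% and 1%; 8 vs 8 with 100 clusters for DS), and three
seeds for the 9-vs-100-cluster resolution comparison. These sizes are the
package's reference configuration: large enough that TPR/FDR and
calibration estimates are stable across seeds, small enough to run
comfortably on a laptop.

## Known limitations

Medians are the only state summary (multimodal shifts inside a cluster can
cancel); clusters are never merged automatically, so phenotype
interpretation is manual, via the heatmaps; strong batch effects can split
clusters across batches; the DS-LMM z reference is approximate at very
small sample counts; and FCS container parsing is out of scope — the
canonical on-disk format is the documented per-sample CSV.
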