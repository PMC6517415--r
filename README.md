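# cytodiscover

Differential discovery in high-dimensional flow and mass cytometry via
high-resolution clustering and empirical Bayes moderated tests.

## Who this is for, and what it does

Multi-sample cytometry experiments (e.g. patients vs. controls, paired
stimulated/unstimulated samples) pose two recurring questions:

* **Differential abundance (DA)** — which cell populations change in
  relative frequency between conditions, including *rare* populations at
  0.1–5% of cells?
* **Differential states (DS)** — within which populations does a functional
  (signaling) marker such as phosphorylated S6 change?

cytodiscover clusters cells on *cell type* markers into a large number of
small clusters with a self-organizing map — deliberately without
meta-clustering, so rare populations are not merged into large neighbors —
then tests cluster-level features with statistics adapted from
transcriptomics:

| method | feature | model |
|---|---|---|
| `run_da_nb` | cluster cell counts | NB GLM, common Cox–Reid dispersion, LRT |
| `run_da_weighted_lm` | log2-CPM counts | mean–variance precision weights + moderated t |
| `run_da_glmm` | counts / totals | binomial GLMM (Laplace) with OLRE, Wald or LRT |
| `run_ds_moderated` | median state-marker expression | weighted LM, trended variance squeezing, moderated t |
| `run_ds_lmm` | median state-marker expression | per-combination LMM (REML), Satterthwaite t |

Moderation shares variance information across clusters: with one common NB
dispersion phi, cluster counts are tested by likelihood-ratio against a
rotated null design; in the linear routes the per-cluster variance s²_k
with d_k residual df is squeezed toward an empirical Bayes prior,

    s̃²_k = (d0·s0² + d_k·s²_k) / (d0 + d_k),

with (d0, s0²) estimated by matching moments of log s² to a scaled F
distribution, and t̃ = β̂_c / (u_k · s̃_k) referred to t with d_k + d0 df.
Paired designs enter as fixed-effect blocks, random intercepts, or a
consensus within-block correlation; the binomial GLMM adds a per-sample
random intercept ("observation-level random effect") to absorb the
extra-binomial overdispersion of real cohorts.

The package also ships a parametric spike-in benchmark generator (paired
two-condition Gaussian-mixture samples with a rare distinct spiked
population at 5%/1%/0.1%, a state-marker shift benchmark, and matched
nulls) and an evaluation harness (ROC, partial AUC at FPR < 0.2, TPR and
observed FDR at FDR cutoffs, KS null-calibration checks), so the whole
pipeline is testable end to end without external data.

## Worked example

Simulate a 5 vs. 5 paired benchmark with a 5% spiked population, cluster at
high resolution, and test for DA:

```r
library(cytodiscover)

cfg <- sim_config(n_per_group = 5, cells_per_sample = 2000,
                  spike_threshold = 0.05, seed = 7)
sim <- simulate_da_benchmark(cfg)

bundle     <- arcsinh_transform(sim$bundle, transform_params("mass"))
model      <- som_train(bundle, som_params(10, 10, seed = 7))
assignment <- som_assign(model, bundle)
counts     <- compute_counts(assignment, bundle, K = 100)

design   <- build_design(bundle$samples, c("group", "block"))  # paired
contrast <- make_contrast(design, c(group_cond2 = 1))
res      <- run_da_nb(counts, design, contrast)
head(res[order(res$p_adj), ], 3)
#>    cluster effect     p_val     p_adj filtered method
#> 56      56 40.965 8.53e-121 6.73e-119    FALSE  da-nb
#> 17      17 -0.603  2.93e-03  1.16e-01    FALSE  da-nb
#> 30      30 -0.482  1.40e-02  3.70e-01    FALSE  da-nb
```

Cluster 56 is detected overwhelmingly (`effect` is the log2 fold change of
abundance; the huge value reflects a population essentially absent from the
healthy samples). Ground truth confirms it is the spiked population, and
the evaluation harness summarizes performance:

```r
ev <- evaluate_results(res, assignment, sim$truth, K = 100)
ev$at_cutoffs
#>   cutoff n_detected tpr fdr
#> 1   0.01          1   1   0
#> 2   0.05          1   1   0
#> 3   0.10          1   1   0
ev$curves$pauc
#> [1] 1
```

At every FDR cutoff the single truly spiked cluster (>50% spiked cells) is
the single detection: TPR 1 with observed FDR 0, and a perfect partial AUC.
`heatmap_export()` draws the top clusters' phenotypes next to their
per-sample abundances, with significance and truth annotations, and writes
the numeric table behind the plot.

A command-line wrapper over the same functions is installed at
`inst/cli/cytodiscover.R` with subcommands `simulate`, `preprocess`,
`cluster`, `test`, `evaluate`, `heatmap` and `pipeline`, driven by a flat
YAML config.

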