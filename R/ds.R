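# Differential state drivers: tests on per-cluster-sample medians of cell
# state markers, reported per cluster-marker combination with joint BH
# adjustment across all combinations.

ds_combos <- function(medians, keep) {
  sm <- names(medians$marker_class)[medians$marker_class == "cell_state"]
  if (length(sm) == 0L) stop("no cell_state markers to test")
  expand.grid(cluster = medians$cluster_ids, marker = sm,
              KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
}

ds_result <- function(combos, retained, effect, p_val, method) {
  out <- data.frame(cluster = combos$cluster, marker = combos$marker,
                    effect = NA_real_, p_val = NA_real_, p_adj = NA_real_,
                    filtered = !retained, method = method)
  out$effect[retained] <- effect
  out$p_val[retained] <- p_val
  out$p_adj[retained] <- bh_adjust(p_val)
  out
}

#' DS test via moderated linear models with a mean-variance trend
#'
#' For each retained cluster x cell state marker combination, the per-sample
#' median arcsinh expression is modeled with weighted least squares (weights
#' proportional to the cluster-sample cell counts, normalized to mean 1, so
#' medians from more cells count more), optionally with a consensus
#' within-block correlation for paired designs. Variances are squeezed with
#' a trend against the average median expression, moderated t tests are
#' computed, and BH adjustment is applied jointly across all cluster-marker
#' combinations. Cluster-sample combinations with zero cells are dropped per
#' combination.
#'
#' @param medians a `cluster_medians` object.
#' @param counts the matching `cluster_counts`.
#' @param design fixed-effects design matrix.
#' @param contrast contrast vector.
#' @param weights use cluster-sample counts as precision weights.
#' @param block_random use a consensus-correlation random block effect.
#' @param block per-sample block factor (with `block_random`).
#' @param trend use a mean-variance trend in the variance prior.
#' @param filter a [filter_rule()] applied to the counts.
#' @return data.frame with one row per cluster-marker combination:
#'   `cluster`, `marker`, `effect` (difference on the arcsinh scale),
#'   `p_val`, `p_adj`, `filtered`, `method = "ds-mod"`.
#' @export
run_ds_moderated <- function(medians, counts, design, contrast,
                             weights = TRUE, block_random = FALSE, block = NULL,
                             trend = TRUE, filter = filter_rule()) {
  check_testable(contrast)
  keep <- filter_clusters(counts, filter)
  combos <- ds_combos(medians)
  retained <- keep[combos$cluster]
  sub <- combos[retained, , drop = FALSE]
  Y <- t(vapply(seq_len(nrow(sub)), function(i)
    medians$medians[sub$cluster[i], , sub$marker[i]],
    numeric(length(medians$sample_ids))))
  W <- NULL
  if (weights) {
    cw <- counts$counts / mean(counts$counts[keep, , drop = FALSE])
    W <- cw[sub$cluster, , drop = FALSE]
  }
  rho <- NULL
  if (block_random) {
    if (is.null(block)) stop("block_random = TRUE requires a block factor")
    if (all(table(block) < 2L))
      stop("all blocks are singletons; use fixed-effect blocks instead")
    rho <- consensus_correlation(Y, design, block, W)
  }
  fits <- weighted_lm_fit(Y, design, W, contrast,
                          block = if (block_random) block else NULL,
                          correlation = rho)
  ok <- fits$ok
  pr <- squeeze_var(fits$s2[ok], fits$df[ok], covariate = fits$amean[ok],
                    trend = trend)
  mod <- moderated_test(fits[ok, ], pr)
  p <- rep(NA_real_, nrow(fits)); p[ok] <- mod$p_val
  out <- ds_result(combos, retained, fits$beta, p, "ds-mod")
  attr(out, "prior") <- pr[c("d0", "s02")]
  attr(out, "correlation") <- rho
  out
}

#' DS test via linear mixed models per cluster-marker combination
#'
#' One model per retained cluster x cell state marker: the per-sample median
#' arcsinh expression is assumed normal, with block random intercepts for
#' paired designs (an ordinary weighted linear model when no random terms
#' are given) and sample-level weights proportional to the cells per sample.
#' Because each combination is modeled separately, between-cluster count
#' variability cannot be weighted here; only per-sample totals are used.
#' Wald z tests on the contrast, BH adjusted jointly across combinations.
#'
#' @param medians a `cluster_medians` object.
#' @param counts the matching `cluster_counts`.
#' @param formula a [build_formula()] spec (random block intercept for
#'   paired designs; no OLRE here).
#' @param contrast contrast vector over the fixed-effect coefficients.
#' @param filter a [filter_rule()].
#' @return data.frame as in [run_ds_moderated()] with `method = "ds-lmm"`.
#' @export
run_ds_lmm <- function(medians, counts, formula, contrast,
                       filter = filter_rule()) {
  stopifnot(inherits(formula, "cyto_formula"))
  check_testable(contrast)
  keep <- filter_clusters(counts, filter)
  combos <- ds_combos(medians)
  retained <- keep[combos$cluster]
  sub <- combos[retained, , drop = FALSE]
  sw <- counts$lib_sizes / mean(counts$lib_sizes)
  design <- formula$design
  eff <- p <- rep(NA_real_, nrow(sub))
  for (i in seq_len(nrow(sub))) {
    y <- medians$medians[sub$cluster[i], , sub$marker[i]]
    fit <- fit_lmm(y, design, random = formula$random, contrast = contrast,
                   weights = sw)
    eff[i] <- fit$beta
    p[i] <- fit$p_val
  }
  ds_result(combos, retained, eff, p, "ds-lmm")
}
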