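# Differential abundance drivers: three routes from a cluster count matrix
# plus design/contrast to per-cluster results (effect, raw p, BH-adjusted p).

check_testable <- function(contrast) {
  nz <- names(contrast)[contrast != 0]
  if (length(nz) && all(nz == "(Intercept)"))
    stop("contrast touches only the intercept: no testable coefficient")
  invisible(TRUE)
}

da_result <- function(counts, keep, effect, p_val, method) {
  K <- nrow(counts$counts)
  out <- data.frame(cluster = counts$cluster_ids,
                    effect = NA_real_, p_val = NA_real_, p_adj = NA_real_,
                    filtered = !keep, method = method)
  out$effect[keep] <- effect
  out$p_val[keep] <- p_val
  out$p_adj[keep] <- bh_adjust(p_val)
  out
}

#' DA test via negative binomial GLMs with common dispersion
#'
#' Count-based differential abundance: low-count filter, optional TMM
#' normalization (effective library sizes enter as offsets), a common
#' dispersion shared across clusters (the moderation step), then a
#' per-cluster likelihood-ratio test on the contrast with BH adjustment
#' across retained clusters. For paired designs include the block as a fixed
#' effect in the design.
#'
#' @param counts a `cluster_counts` object.
#' @param design fixed-effects design matrix ([build_design()]).
#' @param contrast contrast vector ([make_contrast()]).
#' @param normalize apply TMM factors (default off).
#' @param filter a [filter_rule()].
#' @return data.frame with one row per cluster: `cluster`, `effect` (log2
#'   fold change), `p_val`, `p_adj`, `filtered`, `method`.
#' @export
run_da_nb <- function(counts, design, contrast, normalize = FALSE,
                      filter = filter_rule()) {
  check_testable(contrast)
  keep <- filter_clusters(counts, filter)
  eff_lib <- if (normalize) tmm_factors(counts)$eff_lib_sizes else counts$lib_sizes
  offsets <- log(eff_lib)
  sub <- counts$counts[keep, , drop = FALSE]
  phi <- nb_common_dispersion(sub, design, offsets)
  res <- nb_glm_lrt(sub, design, contrast, phi, offsets)
  out <- da_result(counts, keep, res$logFC, res$p_val, "da-nb")
  attr(out, "dispersion") <- phi
  out
}

#' DA test via precision-weighted moderated linear models
#'
#' Differential abundance on log2-CPM-transformed counts: low-count filter,
#' optional TMM normalization, mean-variance precision weights
#' ([voom_weights()]), optionally a consensus within-block correlation for
#' paired designs ([consensus_correlation()]), weighted least squares per
#' cluster, variance squeezing (constant prior), moderated t tests and BH
#' adjustment.
#'
#' @inheritParams run_da_nb
#' @param block_random model the block as a random effect via the consensus
#'   correlation (requires `block`); otherwise include it as a fixed effect
#'   in the design.
#' @param block per-sample block factor (only used with `block_random`).
#' @return data.frame as in [run_da_nb()] with `method = "da-wlm"`.
#' @export
run_da_weighted_lm <- function(counts, design, contrast, normalize = FALSE,
                               filter = filter_rule(), block_random = FALSE,
                               block = NULL) {
  check_testable(contrast)
  keep <- filter_clusters(counts, filter)
  eff_lib <- if (normalize) tmm_factors(counts)$eff_lib_sizes else counts$lib_sizes
  sub <- counts$counts[keep, , drop = FALSE]
  vw <- voom_weights(sub, design, eff_lib)
  rho <- NULL
  if (block_random) {
    if (is.null(block)) stop("block_random = TRUE requires a block factor")
    if (all(table(block) < 2L))
      stop("all blocks are singletons; use fixed-effect blocks instead")
    rho <- consensus_correlation(vw$y, design, block, vw$weights)
  }
  fits <- weighted_lm_fit(vw$y, design, vw$weights, contrast,
                          block = if (block_random) block else NULL,
                          correlation = rho)
  pr <- squeeze_var(fits$s2[fits$ok], fits$df[fits$ok], trend = FALSE)
  mod <- moderated_test(fits[fits$ok, ], pr)
  p <- rep(NA_real_, nrow(fits)); p[fits$ok] <- mod$p_val
  out <- da_result(counts, keep, fits$beta, p, "da-wlm")
  attr(out, "prior") <- pr[c("d0", "s02")]
  attr(out, "correlation") <- rho
  out
}

#' DA test via binomial GLMMs with observation-level random effects
#'
#' One model per cluster: the cluster count out of the per-sample total is
#' binomial on the logit scale, with a random intercept per sample (OLRE)
#' absorbing extra-binomial overdispersion and optionally a block random
#' intercept for paired designs. Wald z tests on the contrast, BH adjusted.
#' Non-converged clusters are reported with missing p-values.
#'
#' @param counts a `cluster_counts` object.
#' @param formula a [build_formula()] spec (use `olre = TRUE`, the default
#'   recommendation for this route).
#' @param contrast contrast vector over the fixed-effect coefficients.
#' @inheritParams run_da_nb
#' @param test `"wald"` (default) or `"lrt"`. The Wald z collapses under
#'   complete separation (e.g. a spiked population absent from one
#'   condition), where the likelihood-ratio test remains informative.
#' @return data.frame as in [run_da_nb()] with `method = "da-glmm"`; the
#'   effect is the contrast estimate on the logit scale.
#' @export
run_da_glmm <- function(counts, formula, contrast, normalize = FALSE,
                        filter = filter_rule(), test = c("wald", "lrt")) {
  test <- match.arg(test)
  stopifnot(inherits(formula, "cyto_formula"))
  check_testable(contrast)
  keep <- filter_clusters(counts, filter)
  eff_lib <- if (normalize) tmm_factors(counts)$eff_lib_sizes else counts$lib_sizes
  totals <- as.integer(round(eff_lib))
  if (any(totals == 0L))
    warning("sample(s) with zero totals dropped from per-cluster models: ",
            paste(counts$sample_ids[totals == 0L], collapse = ", "))
  sub <- counts$counts[keep, , drop = FALSE]
  design <- formula$design
  nconv <- 0L
  eff <- p <- rep(NA_real_, nrow(sub))
  for (k in seq_len(nrow(sub))) {
    fit <- fit_binomial_glmm(pmin(sub[k, ], totals), totals, design,
                             random = formula$random, contrast = contrast,
                             test = test)
    eff[k] <- fit$beta
    p[k] <- fit$p_val
    if (!isTRUE(fit$ok)) nconv <- nconv + 1L
  }
  if (nconv > 0L)
    msg("run_da_glmm: ", nconv, " cluster(s) flagged (non-convergence/separation)")
  da_result(counts, keep, eff, p, "da-glmm")
}

#' Write a DA/DS results table as TSV
#'
#' @param results a results data.frame from the `run_*` drivers.
#' @param path output path.
#' @export
write_results <- function(results, path) {
  write.table(results, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
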