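#' Trimmed mean of M-values (TMM) normalization factors
#'
#' Composition-robust normalization for cluster count matrices. Relative to a
#' reference sample (the one whose upper-quartile count rate is closest to
#' the mean upper quartile), each sample's factor is the weighted mean of
#' per-cluster log2 rate ratios (M-values) after trimming the most extreme
#' 30% of M-values and 5% of average log abundances (A-values) on each side;
#' weights are inverse asymptotic binomial variances. Factors are rescaled to
#' geometric mean 1, and the effective library size is `lib_size * factor`.
#'
#' @param counts a `cluster_counts` object or K x S count matrix.
#' @param lib_sizes per-sample totals (taken from `counts` if omitted).
#' @param ref_sample optional reference sample (index or name).
#' @return list with `factors` (geometric mean 1) and `eff_lib_sizes`.
#' @export
tmm_factors <- function(counts, lib_sizes = NULL, ref_sample = NULL) {
  if (inherits(counts, "cluster_counts")) {
    lib_sizes <- lib_sizes %||% counts$lib_sizes
    counts <- counts$counts
  }
  lib_sizes <- lib_sizes %||% colSums(counts)
  S <- ncol(counts)
  if (S < 2L) stop("TMM needs at least 2 samples")
  if (any(lib_sizes == 0))
    stop("sample(s) with all-zero counts: ",
         paste(colnames(counts)[lib_sizes == 0], collapse = ", "))
  f75 <- vapply(seq_len(S), function(s)
    quantile(counts[, s] / lib_sizes[s], 0.75, names = FALSE), numeric(1))
  ref <- if (is.null(ref_sample)) which.min(abs(f75 - mean(f75)))
         else if (is.character(ref_sample)) match(ref_sample, colnames(counts))
         else as.integer(ref_sample)
  f <- vapply(seq_len(S), function(s)
    tmm_pair(counts[, s], lib_sizes[s], counts[, ref], lib_sizes[ref]), numeric(1))
  f <- f / exp(mean(log(f)))
  names(f) <- colnames(counts)
  list(factors = f, eff_lib_sizes = lib_sizes * f, ref_sample = ref)
}

# One sample against the reference (Robinson & Oshlack weighted trimmed mean).
tmm_pair <- function(obs, n_obs, ref, n_ref,
                     trim_m = 0.30, trim_a = 0.05) {
  keep <- obs > 0 & ref > 0
  obs <- obs[keep]; ref <- ref[keep]
  if (!length(obs)) return(1)
  m <- log2((obs / n_obs) / (ref / n_ref))
  a <- 0.5 * log2((obs / n_obs) * (ref / n_ref))
  v <- (n_obs - obs) / (n_obs * obs) + (n_ref - ref) / (n_ref * ref)
  if (max(abs(m)) < 1e-6) return(1)
  n <- length(m)
  lo_m <- floor(n * trim_m) + 1; hi_m <- n + 1 - lo_m
  lo_a <- floor(n * trim_a) + 1; hi_a <- n + 1 - lo_a
  rm_ <- rank(m); ra <- rank(a)
  keep2 <- rm_ >= lo_m & rm_ <= hi_m & ra >= lo_a & ra <= hi_a
  if (!any(keep2)) return(1)
  f <- 2^(sum(m[keep2] / v[keep2]) / sum(1 / v[keep2]))
  if (!is.finite(f) || f <= 0) 1 else f
}

#' Log counts per million
#'
#' `log2((count + prior) / (lib + 2 * prior) * 1e6)`; with the default prior
#' of 0.5 this is `log2((count + 0.5) / (lib + 1) * 1e6)`, the transform used
#' for the precision-weighted DA test.
#'
#' @param counts K x S count matrix (or `cluster_counts`).
#' @param eff_lib_sizes per-sample (effective) library sizes.
#' @param prior_count prior count to avoid log of zero.
#' @return K x S matrix of log2-CPM values.
#' @export
log_cpm <- function(counts, eff_lib_sizes = NULL, prior_count = 0.5) {
  if (inherits(counts, "cluster_counts")) {
    eff_lib_sizes <- eff_lib_sizes %||% counts$lib_sizes
    counts <- counts$counts
  }
  stopifnot(all(eff_lib_sizes > 0))
  t(log2(t(counts + prior_count) / (eff_lib_sizes + 2 * prior_count) * 1e6))
}
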