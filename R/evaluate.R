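# Evaluation harness: truth labeling of clusters, ROC / partial AUC,
# TPR and observed FDR at adjusted-p cutoffs, and null-calibration checks.

#' Label clusters from per-cell ground truth
#'
#' A cluster is a true positive iff strictly more than half of its cells
#' carry the truth flag (spiked-in cells for DA benchmarks; the designated
#' population for DS benchmarks via `truth$target_pop`).
#'
#' @param assignment per-cell cluster labels in `1..K`.
#' @param flags per-cell logical truth flags (e.g. `truth$spike` or
#'   `truth$target_pop`).
#' @param K number of clusters.
#' @param threshold purity threshold (strict `>`), default 0.5.
#' @return logical vector of length `K` (empty clusters are `FALSE`).
#' @export
label_clusters <- function(assignment, flags, K = max(assignment), threshold = 0.5) {
  stopifnot(length(assignment) == length(flags))
  tot <- tabulate(assignment, nbins = K)
  pos <- tabulate(assignment[flags], nbins = K)
  tot > 0 & pos / pmax(tot, 1L) > threshold
}

#' ROC curve and partial AUC
#'
#' Threshold sweep over per-unit scores (higher = more significant; use
#' `-log(p)` or `1 - p`), with tied scores grouped. Missing scores are
#' ranked worst and therefore count as undetected at every threshold. The
#' partial AUC integrates TPR over FPR in `[0, fpr_max]` (trapezoids, with
#' interpolation at the cut) and is normalized to `[0, 1]`.
#'
#' @param scores per-unit ranking scores (NA = worst).
#' @param labels per-unit logical truth labels (>= 1 positive and >= 1
#'   negative required).
#' @param fpr_max upper FPR bound for the partial AUC (default 0.2).
#' @return list with `roc` (data.frame of FPR, TPR), `auc`, `pauc`
#'   (normalized).
#' @export
roc_pauc <- function(scores, labels, fpr_max = 0.2) {
  labels <- as.logical(labels)
  npos <- sum(labels); nneg <- sum(!labels)
  if (npos == 0L) stop("no positive units")
  if (nneg == 0L) stop("no negative units")
  scores[is.na(scores)] <- -Inf
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; l <- labels[ord]
  last <- cumsum(rle(s)$lengths)           # group tied scores
  tpr <- c(0, cumsum(l)[last] / npos)
  fpr <- c(0, cumsum(!l)[last] / nneg)
  auc <- sum(diff(fpr) * (tpr[-1] + tpr[-length(tpr)]) / 2)
  # clip at fpr_max with linear interpolation
  if (max(fpr) > fpr_max) {
    i <- which(fpr > fpr_max)[1]
    t_cut <- tpr[i - 1] + (tpr[i] - tpr[i - 1]) *
      (fpr_max - fpr[i - 1]) / (fpr[i] - fpr[i - 1])
    fpr_c <- c(fpr[seq_len(i - 1)], fpr_max)
    tpr_c <- c(tpr[seq_len(i - 1)], t_cut)
  } else {
    fpr_c <- c(fpr, fpr_max); tpr_c <- c(tpr, max(tpr))
  }
  pauc <- sum(diff(fpr_c) * (tpr_c[-1] + tpr_c[-length(tpr_c)]) / 2) / fpr_max
  list(roc = data.frame(fpr = fpr, tpr = tpr), auc = auc, pauc = pauc)
}

#' TPR and observed FDR at adjusted-p cutoffs
#'
#' At each cutoff `c`, units with adjusted p <= c are "detected";
#' TPR = detected positives / all positives, observed
#' FDR = detected negatives / max(1, detected) (0/0 counts as 0).
#' Missing adjusted p-values are never detected.
#'
#' @param p_adj per-unit adjusted p-values.
#' @param labels per-unit logical truth labels.
#' @param cutoffs FDR cutoffs (default 1%, 5%, 10%).
#' @return data.frame with `cutoff`, `n_detected`, `tpr`, `fdr`.
#' @export
tpr_fdr_at_cutoffs <- function(p_adj, labels, cutoffs = c(0.01, 0.05, 0.1)) {
  labels <- as.logical(labels)
  npos <- sum(labels)
  out <- lapply(cutoffs, function(cc) {
    det <- !is.na(p_adj) & p_adj <= cc
    data.frame(cutoff = cc,
               n_detected = sum(det),
               tpr = if (npos > 0) sum(det & labels) / npos else NA_real_,
               fdr = sum(det & !labels) / max(1L, sum(det)))
  })
  do.call(rbind, out)
}

#' Kolmogorov-Smirnov test of p-value uniformity
#'
#' One-sample KS test of the raw p-values against U(0, 1); used to check
#' the null calibration of the differential tests (approximately uniform
#' p-values on no-signal data).
#'
#' @param p raw p-values (missing values removed; at least 20 required).
#' @return list with `statistic` and `p_value`.
#' @export
pvalue_uniformity <- function(p) {
  p <- p[!is.na(p)]
  if (length(p) < 20L) stop("need at least 20 non-missing p-values")
  ks <- suppressWarnings(ks.test(p, "punif"))
  list(statistic = unname(ks$statistic), p_value = unname(ks$p.value))
}

#' Evaluate a results table against ground truth
#'
#' Convenience wrapper combining [label_clusters()], [roc_pauc()] and
#' [tpr_fdr_at_cutoffs()] for a DA (per-cluster) or DS (per cluster-marker)
#' results table. DS rows inherit their cluster's truth label; for DS the
#' positive combinations are restricted to the shifted marker when it is
#' recorded in the truth.
#'
#' @param results a results data.frame from the `run_*` drivers.
#' @param assignment per-cell cluster labels.
#' @param truth the truth data.frame from the simulators.
#' @param K number of clusters.
#' @param level `"cluster"` evaluates per cluster (or cluster-marker
#'   combination) against the >50% rule; `"cell"` lets every cell inherit
#'   its cluster's score and adjusted p and evaluates against the per-cell
#'   truth flags, so small spike fragments do not dominate the metrics.
#' @return list with `labels`, `curves` ([roc_pauc()] output) and `at_cutoffs`.
#' @export
evaluate_results <- function(results, assignment, truth, K,
                             level = c("cluster", "cell")) {
  level <- match.arg(level)
  mode <- attr(truth, "mode") %||% "da"
  flags <- if (mode == "ds") truth$target_pop else truth$spike
  if (level == "cell") {
    if (mode == "ds") {
      shifted <- attr(truth, "shifted_marker")
      results <- results[results$marker == shifted, , drop = FALSE]
    }
    idx <- match(assignment, results$cluster)
    score <- -log10(pmax(results$p_val[idx], 1e-300))
    p_adj <- results$p_adj[idx]
    lab <- flags
  } else {
    cl_lab <- label_clusters(assignment, flags, K)
    lab <- cl_lab[results$cluster]
    if (mode == "ds" && !is.null(results$marker)) {
      shifted <- attr(truth, "shifted_marker")
      if (!is.na(shifted)) lab <- lab & results$marker == shifted
    }
    score <- -log10(pmax(results$p_val, 1e-300))
    p_adj <- results$p_adj
  }
  curves <- roc_pauc(score, lab)
  list(labels = lab, curves = curves,
       at_cutoffs = tpr_fdr_at_cutoffs(p_adj, lab))
}
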