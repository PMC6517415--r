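#' Cluster cell counts per sample
#'
#' Tallies cells into a `K x S` count matrix; clusters that are empty
#' everywhere are kept as all-zero rows so the cluster set is identical
#' across methods. Column sums equal the per-sample cell totals (the
#' "library sizes" used as count-model exposure).
#'
#' @param assignment per-cell labels in `1..K`.
#' @param bundle the matching `cyto_experiment`.
#' @param K number of clusters.
#' @return a `cluster_counts` object: `counts` (K x S), `lib_sizes`,
#'   `cluster_ids`, `sample_ids`.
#' @export
compute_counts <- function(assignment, bundle, K) {
  if (any(assignment < 1L | assignment > K))
    stop("cluster label out of range 1..", K)
  counts <- table(factor(assignment, levels = seq_len(K)), bundle$cell_sample)
  counts <- matrix(as.integer(counts), nrow = K,
                   dimnames = list(seq_len(K), levels(bundle$cell_sample)))
  lib <- colSums(counts)
  if (any(lib == 0L))
    warning("sample(s) with zero cells: ",
            paste(names(lib)[lib == 0L], collapse = ", "))
  structure(list(counts = counts, lib_sizes = lib,
                 cluster_ids = seq_len(K), sample_ids = colnames(counts)),
            class = "cluster_counts")
}

#' Median marker expression per cluster-sample
#'
#' Medians of arcsinh-transformed expression, one value per cluster x sample
#' x marker (even cell counts use the mean of the two middle order
#' statistics). Cluster-sample combinations with zero cells are `NA`.
#'
#' @param assignment per-cell labels in `1..K`.
#' @param bundle an arcsinh-transformed `cyto_experiment`.
#' @param markers marker names to summarize; defaults to all cell_type and
#'   cell_state markers.
#' @param K number of clusters (defaults to `max(assignment)`).
#' @return a `cluster_medians` object wrapping a `K x S x M` array with a
#'   `marker_class` attribute per slice.
#' @export
compute_medians <- function(assignment, bundle, markers = NULL, K = max(assignment)) {
  if (bundle$transform$state != "arcsinh")
    stop("medians are computed on arcsinh-transformed expression")
  if (is.null(markers))
    markers <- bundle$markers$marker_id[bundle$markers$marker_class != "none"]
  S <- nlevels(bundle$cell_sample)
  med <- array(NA_real_, dim = c(K, S, length(markers)),
               dimnames = list(seq_len(K), levels(bundle$cell_sample), markers))
  grp <- interaction(factor(assignment, levels = seq_len(K)),
                     bundle$cell_sample, drop = FALSE)
  for (m in markers) {
    v <- vapply(split(bundle$exprs[, m], grp), function(x)
      if (length(x)) median(x) else NA_real_, numeric(1))
    med[, , m] <- matrix(v, nrow = K)
  }
  cls <- bundle$markers$marker_class[match(markers, bundle$markers$marker_id)]
  structure(list(medians = med, marker_class = setNames(cls, markers),
                 cluster_ids = seq_len(K), sample_ids = levels(bundle$cell_sample)),
            class = "cluster_medians")
}

#' Per-cluster medians pooled over all samples
#'
#' Medians over all cells of each cluster regardless of sample; used for the
#' phenotype (left) panel of results heatmaps.
#'
#' @inheritParams compute_medians
#' @return `K x M` matrix (NA for empty clusters).
#' @export
pooled_medians <- function(assignment, bundle, markers = NULL, K = max(assignment)) {
  if (is.null(markers)) markers <- type_markers(bundle)
  out <- matrix(NA_real_, K, length(markers), dimnames = list(seq_len(K), markers))
  grp <- factor(assignment, levels = seq_len(K))
  for (m in markers) {
    v <- vapply(split(bundle$exprs[, m], grp), function(x)
      if (length(x)) median(x) else NA_real_, numeric(1))
    out[, m] <- v
  }
  out
}

#' Low-count cluster filter
#'
#' A cluster is retained iff it has at least `min_cells` cells in at least
#' `min_samples` samples. The defaults (3 cells in at least half the samples)
#' are deliberately permissive so rare populations survive; on well-behaved
#' benchmark data the filter typically removes nothing.
#'
#' @param min_cells minimum cells per cluster-sample.
#' @param min_samples minimum number of samples meeting `min_cells`;
#'   `NULL` for the default `floor(S/2)` resolved at filter time.
#' @return a `filter_rule` object.
#' @export
filter_rule <- function(min_cells = 3L, min_samples = NULL) {
  stopifnot(min_cells >= 0L)
  structure(list(min_cells = as.integer(min_cells),
                 min_samples = if (is.null(min_samples)) NULL else as.integer(min_samples)),
            class = "filter_rule")
}

#' Apply a low-count filter to cluster counts
#'
#' @param counts a `cluster_counts` object.
#' @param rule a [filter_rule()].
#' @return logical vector of length K, `TRUE` for retained clusters.
#' @export
filter_clusters <- function(counts, rule = filter_rule()) {
  S <- ncol(counts$counts)
  min_samples <- rule$min_samples %||% (S %/% 2L)
  if (min_samples < 0L || min_samples > S)
    stop("min_samples must be in 0..", S)
  keep <- rowSums(counts$counts >= rule$min_cells) >= min_samples
  if (!any(keep))
    stop("all clusters removed by the low-count filter; relax min_cells/min_samples")
  removed <- sum(!keep)
  if (removed > 0)
    msg("filter_clusters: removed ", removed, " of ", length(keep), " clusters")
  keep
}

#' Export cluster features as TSV
#'
#' Counts as a clusters x samples table; medians in long format
#' (cluster, sample, marker, value).
#'
#' @param counts a `cluster_counts`.
#' @param medians a `cluster_medians` (optional).
#' @param dir output directory.
#' @export
write_features <- function(counts, medians = NULL, dir = ".") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write.table(data.frame(cluster = rownames(counts$counts), counts$counts,
                         check.names = FALSE),
              file.path(dir, "counts.tsv"), sep = "\t", row.names = FALSE, quote = FALSE)
  if (!is.null(medians)) {
    long <- as.data.frame.table(medians$medians, responseName = "value")
    names(long)[1:3] <- c("cluster", "sample", "marker")
    write.table(long, file.path(dir, "medians.tsv"), sep = "\t",
                row.names = FALSE, quote = FALSE)
  }
  invisible(dir)
}
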