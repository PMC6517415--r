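# Results heatmap: cluster phenotypes (pooled cell type marker medians) next
# to the per-sample signal of interest (relative abundance for DA, state
# marker median for DS), for the top most significant units.

#' Heatmap of top differential clusters / cluster-marker combinations
#'
#' Selects the `top_n` units with the smallest adjusted p-values. For DA
#' results the rows are clusters, grouped by hierarchical clustering of
#' their phenotype (Euclidean distance, average linkage) and the per-sample
#' panel shows relative abundances; for DS results the rows are
#' cluster-marker combinations ordered by significance and the per-sample
#' panel shows the state-marker medians. Row annotations mark units
#' significant at the FDR cutoff and, when truth labels are supplied,
#' clusters containing >50% spiked cells. The phenotype color scale is
#' clipped at the 1st/99th percentiles. The numeric table underlying the
#' heatmap is always written next to the image so every plotted value is
#' reproducible.
#'
#' @param results DA or DS results data.frame.
#' @param medians a `cluster_medians` (per-sample panel for DS).
#' @param counts a `cluster_counts` (per-sample panel for DA).
#' @param pooled K x M matrix of pooled cell-type-marker medians
#'   ([pooled_medians()]).
#' @param top_n number of units to display (capped at the available units,
#'   with a warning).
#' @param fdr significance cutoff for the annotation.
#' @param truth optional logical vector of length K of true differential
#'   clusters.
#' @param file optional PNG path; the table goes to
#'   `<file without extension>_table.tsv` (or is only returned when `file`
#'   is `NULL`).
#' @return invisibly, the underlying table (one row per displayed unit).
#' @export
heatmap_export <- function(results, medians, counts, pooled, top_n = 20L,
                           fdr = 0.1, truth = NULL, file = NULL) {
  is_ds <- "marker" %in% names(results)
  avail <- sum(!is.na(results$p_adj))
  if (top_n > avail) {
    warning("top_n (", top_n, ") exceeds available units (", avail, "); using all")
    top_n <- avail
  }
  ord <- order(results$p_adj)[seq_len(top_n)]
  top <- results[ord, , drop = FALSE]
  pheno <- pooled[top$cluster, , drop = FALSE]
  if (is_ds) {
    signal <- t(vapply(seq_len(nrow(top)), function(i)
      medians$medians[top$cluster[i], , top$marker[i]],
      numeric(length(medians$sample_ids))))
    colnames(signal) <- medians$sample_ids
    rn <- paste0("c", top$cluster, ":", top$marker)
  } else {
    prop <- sweep(counts$counts, 2, pmax(counts$lib_sizes, 1L), "/")
    signal <- prop[top$cluster, , drop = FALSE]
    rn <- paste0("c", top$cluster)
    # group DA rows by phenotype similarity
    if (nrow(pheno) > 2L) {
      hc <- hclust(dist(pheno), method = "average")
      top <- top[hc$order, , drop = FALSE]
      pheno <- pheno[hc$order, , drop = FALSE]
      signal <- signal[hc$order, , drop = FALSE]
      rn <- rn[hc$order]
    }
  }
  sig <- !is.na(top$p_adj) & top$p_adj <= fdr
  tru <- if (!is.null(truth)) truth[top$cluster] else NA
  tab <- data.frame(unit = rn, top, significant = sig, true_differential = tru,
                    pheno, signal, check.names = FALSE)
  if (!is.null(file)) {
    write.table(tab, paste0(sub("\\.[A-Za-z]+$", "", file), "_table.tsv"),
                sep = "\t", row.names = FALSE, quote = FALSE)
    draw_heatmap(pheno, signal, rn, sig, tru, is_ds, file)
  }
  invisible(tab)
}

draw_heatmap <- function(pheno, signal, rn, sig, tru, is_ds, file) {
  if (!requireNamespace("ComplexHeatmap", quietly = TRUE)) {
    warning("ComplexHeatmap not available; wrote table only")
    return(invisible(NULL))
  }
  lim <- quantile(pheno, c(0.01, 0.99), na.rm = TRUE)
  pheno_c <- pmin(pmax(pheno, lim[1]), lim[2])
  rownames(pheno_c) <- rownames(signal) <- rn
  ann <- ComplexHeatmap::rowAnnotation(
    significant = factor(ifelse(sig, "yes", "no"), c("no", "yes")),
    true = if (all(is.na(tru))) NULL
           else factor(ifelse(tru, "yes", "no"), c("no", "yes")),
    col = list(significant = c(no = "grey90", yes = "red"),
               true = c(no = "grey90", yes = "black")))
  h1 <- ComplexHeatmap::Heatmap(pheno_c, name = "phenotype",
                                cluster_rows = FALSE, cluster_columns = FALSE)
  h2 <- ComplexHeatmap::Heatmap(signal,
                                name = if (is_ds) "median" else "abundance",
                                cluster_rows = FALSE, cluster_columns = FALSE,
                                right_annotation = ann)
  grDevices::png(file, width = 1400, height = 200 + 28 * nrow(pheno_c), res = 120)
  on.exit(grDevices::dev.off())
  ComplexHeatmap::draw(h1 + h2)
  invisible(NULL)
}
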