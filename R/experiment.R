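#' Marker metadata table
#'
#' Builds and validates the marker metadata used throughout the package. Each
#' marker is assigned a class: `"cell_type"` markers define stable cell
#' identity and are used for clustering; `"cell_state"` markers capture
#' transient functional states (e.g. phosphorylated signaling proteins) and are
#' summarized as per-cluster medians for differential state testing; `"none"`
#' markers are carried along for provenance but not analyzed.
#'
#' @param marker_id character vector of unique marker names.
#' @param marker_class character vector, one of `"cell_type"`, `"cell_state"`,
#'   `"none"`.
#' @param channel optional character vector of acquisition channel names used
#'   for file-column matching when column names differ from marker names.
#' @return a `data.frame` with columns `marker_id`, `marker_class`, `channel`.
#' @export
marker_info <- function(marker_id, marker_class, channel = NA_character_) {
  marker_id <- as.character(marker_id)
  if (anyDuplicated(marker_id))
    stop("marker names must be unique")
  marker_class <- match.arg(as.character(marker_class),
                            c("cell_type", "cell_state", "none"),
                            several.ok = TRUE)
  if (length(marker_class) == 1L)
    marker_class <- rep(marker_class, length(marker_id))
  stopifnot(length(marker_class) == length(marker_id))
  data.frame(marker_id = marker_id,
             marker_class = marker_class,
             channel = rep_len(as.character(channel), length(marker_id)),
             stringsAsFactors = FALSE)
}

#' Sample metadata table
#'
#' One row per biological sample. `group_id` is the condition of interest
#' (at least two levels are needed for a two-group contrast); `block_id`
#' identifies paired/blocked units such as patients; `batch_id` and extra
#' numeric `covariate_*` columns can be adjusted for in the design.
#'
#' @param sample_id unique sample identifiers.
#' @param group_id condition labels (coerced to factor, first observed level
#'   is the reference).
#' @param block_id,batch_id optional factors.
#' @param ... optional named numeric covariates (stored as `covariate_<name>`).
#' @return a `data.frame` of sample metadata.
#' @export
sample_info <- function(sample_id, group_id, block_id = NULL, batch_id = NULL, ...) {
  sample_id <- as.character(sample_id)
  if (anyDuplicated(sample_id)) stop("sample_ids must be unique")
  out <- data.frame(sample_id = sample_id,
                    group_id = factor(group_id, levels = unique(as.character(group_id))),
                    stringsAsFactors = FALSE)
  if (!is.null(block_id)) out$block_id <- factor(block_id, levels = unique(as.character(block_id)))
  if (!is.null(batch_id)) out$batch_id <- factor(batch_id, levels = unique(as.character(batch_id)))
  covs <- list(...)
  if (length(covs)) {
    if (is.null(names(covs)) || any(names(covs) == ""))
      stop("covariates must be named")
    for (nm in names(covs)) {
      v <- covs[[nm]]
      if (!is.numeric(v)) stop("covariate '", nm, "' must be numeric")
      out[[paste0("covariate_", sub("^covariate_", "", nm))]] <- v
    }
  }
  out
}

new_experiment <- function(exprs, cell_sample, markers, samples,
                           transform = list(state = "raw", cofactor = NA_real_)) {
  stopifnot(is.matrix(exprs))
  cell_sample <- factor(as.character(cell_sample), levels = samples$sample_id)
  if (anyNA(cell_sample))
    stop("every cell's sample must appear in the sample table")
  if (ncol(exprs) != nrow(markers))
    stop("expression column count (", ncol(exprs),
         ") does not equal marker count (", nrow(markers), ")")
  if (any(!is.finite(exprs)))
    stop("expression matrix contains non-finite values")
  colnames(exprs) <- markers$marker_id
  structure(list(exprs = exprs,
                 cell_sample = cell_sample,
                 markers = markers,
                 samples = samples,
                 transform = transform),
            class = "cyto_experiment")
}

#' @export
print.cyto_experiment <- function(x, ...) {
  cat("cyto_experiment:", nrow(x$exprs), "cells x", ncol(x$exprs), "markers\n")
  cat("  samples:", nrow(x$samples),
      " (groups: ", paste(levels(x$samples$group_id), collapse = ", "), ")\n", sep = "")
  cls <- table(factor(x$markers$marker_class, c("cell_type", "cell_state", "none")))
  cat("  markers: ", cls[["cell_type"]], " cell_type, ", cls[["cell_state"]],
      " cell_state, ", cls[["none"]], " none\n", sep = "")
  cat("  transform:", x$transform$state,
      if (x$transform$state == "arcsinh") paste0("(cofactor ", x$transform$cofactor, ")"),
      "\n")
  invisible(x)
}

type_markers <- function(bundle) bundle$markers$marker_id[bundle$markers$marker_class == "cell_type"]
state_markers <- function(bundle) bundle$markers$marker_id[bundle$markers$marker_class == "cell_state"]

# Resolve CSV columns against the marker table: match marker names first, then
# the channel strings; ambiguity is an error, never a guess.
match_columns <- function(cols, markers, file) {
  idx <- match(markers$marker_id, cols)
  miss <- is.na(idx)
  if (any(miss) && !all(is.na(markers$channel))) {
    idx2 <- match(markers$channel[miss], cols)
    idx[miss] <- idx2
  }
  if (anyNA(idx))
    stop("file '", file, "': no column found for marker(s) ",
         paste(markers$marker_id[is.na(idx)], collapse = ", "))
  if (anyDuplicated(idx))
    stop("file '", file, "': ambiguous column mapping (a column matches more than one marker)")
  idx
}

#' Load a cytometry experiment from per-sample CSV files
#'
#' Reads one CSV per sample (header row of marker names, one optional leading
#' `sample_id` column) and concatenates them into a single cells x markers
#' expression matrix with per-cell sample IDs. Cells containing any non-finite
#' value are rejected at load time, with a reported count. Expression values
#' are kept on the raw scale; apply [arcsinh_transform()] before clustering.
#'
#' @param files character vector of CSV paths, one per sample, in
#'   `sample_table` order (or named by `sample_id`).
#' @param marker_table data.frame from [marker_info()] (or
#'   [read_marker_table()]).
#' @param sample_table data.frame from [sample_info()] (or
#'   [read_sample_table()]).
#' @return a `cyto_experiment` bundle.
#' @export
load_experiment <- function(files, marker_table, sample_table) {
  stopifnot(is.data.frame(marker_table), is.data.frame(sample_table))
  if (!all(c("marker_id", "marker_class") %in% names(marker_table)))
    stop("marker_table needs columns marker_id, marker_class")
  if (is.null(marker_table$channel)) marker_table$channel <- NA_character_
  if (length(files) != nrow(sample_table))
    stop("need one file per sample (", nrow(sample_table), " samples, ",
         length(files), " files)")
  if (!is.null(names(files)) && all(nzchar(names(files)))) {
    unknown <- setdiff(names(files), sample_table$sample_id)
    if (length(unknown))
      stop("file(s) for unknown sample(s): ", paste(unknown, collapse = ", "))
    files <- files[sample_table$sample_id]
  }
  mats <- vector("list", length(files))
  dropped <- 0L
  for (i in seq_along(files)) {
    f <- files[[i]]
    if (!file.exists(f) || file.size(f) == 0)
      stop("empty or missing file: '", f, "'")
    tab <- read.csv(f, check.names = FALSE)
    if (ncol(tab) && names(tab)[1] == "sample_id") tab <- tab[, -1, drop = FALSE]
    idx <- match_columns(names(tab), marker_table, f)
    m <- as.matrix(tab[, idx, drop = FALSE])
    storage.mode(m) <- "double"
    if (nrow(m)) {
      bad <- !apply(is.finite(m), 1L, all)
      dropped <- dropped + sum(bad)
      m <- m[!bad, , drop = FALSE]
    }
    colnames(m) <- marker_table$marker_id
    mats[[i]] <- m
  }
  if (dropped > 0L)
    msg("load_experiment: rejected ", dropped, " cell(s) with non-finite values")
  exprs <- do.call(rbind, mats)
  cell_sample <- rep(sample_table$sample_id, vapply(mats, nrow, 1L))
  new_experiment(exprs, cell_sample, marker_table, sample_table)
}

#' Write an experiment to disk as per-sample CSV fixtures
#'
#' One CSV per sample (marker-name header, leading `sample_id` column) plus
#' `markers.tsv` and `samples.tsv` metadata tables; the result is reloadable
#' with [load_experiment()]. Channel ordering is identical across samples.
#'
#' @param bundle a `cyto_experiment`.
#' @param path directory to write into (created if needed).
#' @return invisibly, the vector of cell-table file paths (named by sample).
#' @export
write_fixture <- function(bundle, path) {
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(path)) stop("cannot create directory '", path, "'")
  paths <- character(nrow(bundle$samples))
  names(paths) <- bundle$samples$sample_id
  for (s in bundle$samples$sample_id) {
    keep <- bundle$cell_sample == s
    tab <- data.frame(sample_id = rep(s, sum(keep)), check.names = FALSE)
    tab <- cbind(tab, as.data.frame(bundle$exprs[keep, , drop = FALSE]))
    f <- file.path(path, paste0(s, ".csv"))
    write.csv(tab, f, row.names = FALSE)
    paths[[s]] <- f
  }
  write.table(bundle$markers, file.path(path, "markers.tsv"),
              sep = "\t", row.names = FALSE, quote = FALSE)
  write.table(bundle$samples, file.path(path, "samples.tsv"),
              sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(paths)
}

#' Read marker / sample metadata tables (TSV)
#'
#' `read_marker_table()` expects columns `marker_id`, `marker_class` and
#' optionally `channel`; `read_sample_table()` expects `sample_id`,
#' `group_id` and optionally `block_id`, `batch_id` and numeric
#' `covariate_*` columns.
#'
#' @param path TSV file path.
#' @return a validated metadata `data.frame`.
#' @export
read_marker_table <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  marker_info(tab$marker_id, tab$marker_class, tab$channel %||% NA_character_)
}

#' @rdname read_marker_table
#' @export
read_sample_table <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  covs <- tab[grepl("^covariate_", names(tab))]
  do.call(sample_info, c(list(sample_id = tab$sample_id, group_id = tab$group_id,
                              block_id = tab$block_id, batch_id = tab$batch_id),
                         as.list(covs)))
}
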