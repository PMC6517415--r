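#' Self-organizing map parameters
#'
#' The SOM grid size is the main user choice: the total number of clusters is
#' `xdim * ydim` (default 10 x 10 = 100). High-resolution grids (100-400
#' nodes, up to 40 x 40 = 1600 for resolution sweeps) keep rare populations in
#' their own clusters instead of merging them into larger ones; no
#' meta-clustering is performed. Learning rate and neighborhood radius decay
#' linearly over `rlen` passes through the data; the default radius starts at
#' half the grid diagonal and shrinks to 0 (BMU-only updates at the end).
#'
#' @param xdim,ydim grid dimensions (integers >= 2).
#' @param rlen number of passes through the data.
#' @param alpha length-2 decreasing learning-rate range.
#' @param radius length-2 decreasing neighborhood-radius range, in grid
#'   units; `NULL` for the default (half grid diagonal down to 0).
#' @param seed integer seed controlling codebook initialization and the
#'   per-pass presentation shuffle.
#' @return an object of class `som_params`.
#' @export
som_params <- function(xdim = 10L, ydim = 10L, rlen = 10L,
                       alpha = c(0.05, 0.01), radius = NULL, seed = 1L) {
  xdim <- as.integer(xdim); ydim <- as.integer(ydim)
  stopifnot(xdim >= 2L, ydim >= 2L, rlen >= 1L,
            length(alpha) == 2L, alpha[1] >= alpha[2], alpha[2] > 0)
  if (is.null(radius))
    radius <- c(0.5 * sqrt((xdim - 1)^2 + (ydim - 1)^2), 0)
  stopifnot(length(radius) == 2L, radius[1] >= radius[2])
  structure(list(xdim = xdim, ydim = ydim, K = xdim * ydim, rlen = as.integer(rlen),
                 alpha = alpha, radius = radius, seed = as.integer(seed)),
            class = "som_params")
}

som_grid <- function(params) {
  k <- seq_len(params$K) - 1L
  cbind(x = k %% params$xdim + 1L, y = k %/% params$xdim + 1L)
}

#' Train a self-organizing map on cell type markers
#'
#' Online SOM training on the arcsinh-transformed expression of the cell type
#' markers only (cell state markers are deliberately excluded so that the
#' clustering is blind to the tested signal). Values are not rescaled before
#' training: the arcsinh transform already stabilizes scale across markers.
#' The codebook is initialized from `K` randomly chosen cells and cells are
#' presented in a freshly shuffled order on each pass; everything is
#' deterministic given `params$seed`.
#'
#' @param bundle an arcsinh-transformed `cyto_experiment`.
#' @param params from [som_params()].
#' @return a `som_model` with the `K x M_type` codebook, the grid
#'   coordinates, and the parameters used.
#' @export
som_train <- function(bundle, params = som_params()) {
  stopifnot(inherits(bundle, "cyto_experiment"))
  if (bundle$transform$state != "arcsinh")
    stop("bundle must be arcsinh-transformed before clustering")
  tm <- type_markers(bundle)
  if (length(tm) == 0L)
    stop("no cell_type markers available for clustering")
  X <- bundle$exprs[, tm, drop = FALSE]
  n <- nrow(X)
  if (n < params$K)
    warning("fewer cells (", n, ") than SOM nodes (", params$K, ")")
  grid <- som_grid(params)
  gd <- as.matrix(dist(grid))
  with_substream(params$seed, "som", {
    init <- X[sample.int(n, params$K, replace = n < params$K), , drop = FALSE]
    ord <- unlist(lapply(seq_len(params$rlen), function(i) sample.int(n))) - 1L
    codebook <- som_train_cpp(X, init, ord, gd,
                              params$alpha[1], params$alpha[2],
                              params$radius[1], params$radius[2])
  })
  dimnames(codebook) <- list(NULL, tm)
  structure(list(codebook = codebook, grid = grid, markers = tm, params = params),
            class = "som_model")
}

#' @export
print.som_model <- function(x, ...) {
  cat("som_model:", x$params$xdim, "x", x$params$ydim, "grid (",
      x$params$K, "clusters ) on", length(x$markers), "cell_type markers\n")
  invisible(x)
}

#' Assign cells to SOM clusters
#'
#' Labels each cell with the nearest codebook node (Euclidean distance; ties
#' broken by the lowest node index). Assignment is a pure nearest-neighbor
#' scan, so re-assigning with a fixed model is stable.
#'
#' @param model a `som_model`.
#' @param bundle a `cyto_experiment` containing the model's markers.
#' @return integer vector of per-cell labels in `1..K`.
#' @export
som_assign <- function(model, bundle) {
  stopifnot(inherits(model, "som_model"), inherits(bundle, "cyto_experiment"))
  missing <- setdiff(model$markers, colnames(bundle$exprs))
  if (length(missing))
    stop("bundle lacks model marker(s): ", paste(missing, collapse = ", "))
  som_map_cpp(bundle$exprs[, model$markers, drop = FALSE], model$codebook)
}

#' Export per-cell cluster labels as TSV
#'
#' Writes `cell_index`, `sample_id`, `cluster` so labels can be used by
#' external tools.
#'
#' @param assignment per-cell labels from [som_assign()].
#' @param bundle the matching `cyto_experiment`.
#' @param path output TSV path.
#' @export
write_labels <- function(assignment, bundle, path) {
  tab <- data.frame(cell_index = seq_along(assignment),
                    sample_id = as.character(bundle$cell_sample),
                    cluster = assignment)
  write.table(tab, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
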