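#' Transformation parameters
#'
#' Raw cytometry intensities are approximately log-normal; the inverse
#' hyperbolic sine `asinh(x / cofactor)` behaves like a log at high values but
#' stays approximately linear (and odd-symmetric) near zero, so zeros and the
#' small negatives produced by instrument background subtraction are handled
#' gracefully. The cofactor sets the width of the linear region; standard
#' values are 5 for mass cytometry and 150 for fluorescence flow cytometry.
#'
#' @param modality `"mass"` or `"flow"`; selects the default cofactor.
#' @param cofactor optional explicit positive cofactor, overrides the
#'   modality default.
#' @return list with elements `modality` and `cofactor`.
#' @export
transform_params <- function(modality = c("mass", "flow"), cofactor = NULL) {
  modality <- match.arg(modality)
  if (is.null(cofactor)) cofactor <- if (modality == "mass") 5 else 150
  if (!is.numeric(cofactor) || length(cofactor) != 1L || cofactor <= 0)
    stop("cofactor must be a single positive number")
  list(modality = modality, cofactor = cofactor)
}

#' Arcsinh-transform an experiment
#'
#' Applies `asinh(x / cofactor)` elementwise and marks the bundle as
#' transformed. Transforming twice is an error.
#'
#' @param bundle a `cyto_experiment` with `transform$state == "raw"`.
#' @param params from [transform_params()].
#' @return the transformed `cyto_experiment`.
#' @export
arcsinh_transform <- function(bundle, params = transform_params()) {
  stopifnot(inherits(bundle, "cyto_experiment"))
  if (bundle$transform$state != "raw")
    stop("bundle is already transformed (state '", bundle$transform$state, "')")
  if (params$cofactor <= 0) stop("cofactor must be > 0")
  bundle$exprs <- asinh(bundle$exprs / params$cofactor)
  bundle$transform <- list(state = "arcsinh", cofactor = params$cofactor)
  bundle
}

#' Equal-size subsampling of cells per sample
#'
#' Draws exactly `n_per_sample` cells uniformly without replacement from each
#' sample. Subsampling is opt-in and never applied by default: discarding
#' cells loses information, which is most damaging for rare populations.
#'
#' @param bundle a `cyto_experiment`.
#' @param n_per_sample number of cells to keep per sample; must not exceed
#'   the smallest sample (an error, never a silent cap).
#' @param seed integer seed (drawn from its own named substream so it does
#'   not perturb SOM training).
#' @return the subsampled `cyto_experiment`; cell order within samples is
#'   preserved.
#' @export
subsample_equal <- function(bundle, n_per_sample, seed = 1L) {
  stopifnot(inherits(bundle, "cyto_experiment"))
  sizes <- table(bundle$cell_sample)
  if (n_per_sample > min(sizes))
    stop("n_per_sample (", n_per_sample, ") exceeds smallest sample (",
         min(sizes), ")")
  keep <- logical(nrow(bundle$exprs))
  with_substream(seed, "subsample", {
    for (s in levels(bundle$cell_sample)) {
      idx <- which(bundle$cell_sample == s)
      keep[sort(sample(idx, n_per_sample))] <- TRUE
    }
  })
  bundle$exprs <- bundle$exprs[keep, , drop = FALSE]
  bundle$cell_sample <- bundle$cell_sample[keep]
  bundle
}
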