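#' Build a fixed-effects design matrix
#'
#' One row per sample, in sample-table order. Categorical terms are
#' treatment-coded with an explicit intercept (first observed level is the
#' reference), and columns are laid out deterministically: intercept, group
#' levels, block levels, batch levels, then continuous covariates.
#' Confounded terms produce an error naming the collinear columns.
#'
#' @param samples a sample metadata `data.frame` ([sample_info()]).
#' @param terms character vector of terms among `"group"`, `"block"`,
#'   `"batch"`, and covariate names (with or without the `covariate_`
#'   prefix).
#' @return a numeric design matrix with a `"terms"` attribute.
#' @export
build_design <- function(samples, terms = "group") {
  S <- nrow(samples)
  cols <- list("(Intercept)" = rep(1, S))
  canon <- c(group = "group_id", block = "block_id", batch = "batch_id")
  for (tm in terms) {
    col <- if (tm %in% names(canon)) canon[[tm]]
           else if (tm %in% names(samples)) tm
           else paste0("covariate_", tm)
    if (!col %in% names(samples))
      stop("term '", tm, "' not found in sample metadata")
    v <- samples[[col]]
    if (is.factor(v) || is.character(v)) {
      v <- factor(v, levels = unique(as.character(v)))
      for (lv in levels(v)[-1])
        cols[[paste0(sub("_id$", "", col), "_", lv)]] <- as.numeric(v == lv)
    } else {
      cols[[sub("^covariate_", "", col)]] <- as.numeric(v)
    }
  }
  X <- do.call(cbind, cols)
  rownames(X) <- samples$sample_id
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    bad <- colnames(X)[qx$pivot[(qx$rank + 1L):ncol(X)]]
    stop("design is rank deficient; collinear column(s): ",
         paste(bad, collapse = ", "))
  }
  attr(X, "terms") <- terms
  X
}

#' Model formula with random-intercept terms
#'
#' Describes fixed terms plus optional random intercepts: a blocking factor
#' (e.g. patient in a paired design) and/or observation-level random effects
#' (OLRE, one random intercept per sample) which absorb the extra-binomial
#' overdispersion typical of cytometry cluster counts (DA GLMM only).
#'
#' @param samples sample metadata.
#' @param fixed character vector of fixed terms (as in [build_design()]);
#'   must be non-empty.
#' @param random character vector of random-intercept factors (typically
#'   `"block"`).
#' @param olre add a per-sample random intercept.
#' @return a `cyto_formula` object with the fixed-effects design matrix and
#'   random-term factor list.
#' @export
build_formula <- function(samples, fixed = "group", random = character(), olre = FALSE) {
  if (length(fixed) == 0L) stop("at least one fixed term is required")
  overlap <- intersect(fixed, random)
  if (length(overlap))
    stop("term(s) in both fixed and random: ", paste(overlap, collapse = ", "))
  design <- build_design(samples, fixed)
  canon <- c(group = "group_id", block = "block_id", batch = "batch_id")
  rterms <- list()
  for (tm in random) {
    col <- if (tm %in% names(canon)) canon[[tm]] else tm
    if (!col %in% names(samples)) stop("random term '", tm, "' not in sample metadata")
    f <- factor(samples[[col]])
    if (nlevels(f) < 2L) stop("random term '", tm, "' has a single level")
    rterms[[tm]] <- f
  }
  if (olre)
    rterms[["olre"]] <- factor(samples$sample_id, levels = samples$sample_id)
  structure(list(design = design, random = rterms, olre = olre,
                 fixed = fixed, samples = samples),
            class = "cyto_formula")
}

#' Contrast vector over design coefficients
#'
#' The contrast is the combination of model coefficients assumed to be zero
#' under the null. Coefficients are addressed by design column name so the
#' contrast is robust to factor coding.
#'
#' @param design a design matrix (or `cyto_formula`).
#' @param weights named numeric vector/list of coefficient weights, e.g.
#'   `c(group_cond2 = 1)`.
#' @return numeric contrast vector of length `ncol(design)`.
#' @export
make_contrast <- function(design, weights) {
  if (inherits(design, "cyto_formula")) design <- design$design
  w <- unlist(weights)
  if (length(w) == 0L || all(w == 0)) stop("contrast weights must not be all zero")
  unknown <- setdiff(names(w), colnames(design))
  if (length(unknown))
    stop("unknown coefficient(s): ", paste(unknown, collapse = ", "))
  contrast <- setNames(numeric(ncol(design)), colnames(design))
  contrast[names(w)] <- w
  contrast
}

# Orthogonal reparameterization used by every test: rotate the design so the
# (normalized) contrast becomes the last coefficient, which all methods then
# test against zero. This gives uniform null semantics across methods.
reparam_contrast <- function(design, contrast) {
  P <- ncol(design)
  cn <- contrast / sqrt(sum(contrast^2))
  Q <- qr.Q(qr(cbind(cn, diag(P))))[, seq_len(P), drop = FALSE]
  # first column of Q is +-cn; fix sign so the tested coefficient is c'beta
  if (sum(Q[, 1] * cn) < 0) Q[, 1] <- -Q[, 1]
  Q <- Q[, c(seq_len(P)[-1], 1L), drop = FALSE]  # contrast coef goes last
  Xstar <- design %*% Q
  colnames(Xstar) <- c(paste0("nuis", seq_len(P - 1L)), "contrast")
  # beta* = t(Q) beta, so last coef of the rotated model is cn' beta
  list(design = Xstar, scale = sqrt(sum(contrast^2)))
}
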