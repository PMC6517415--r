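#' @useDynLib cytodiscover, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats approx dbinom dnbinom lowess median optim optimise
#'   pchisq pnorm pt qlogis quantile rnorm runif rmultinom sd var
#'   model.matrix p.adjust ks.test plogis rgamma glm.fit poisson binomial
#'   lm.wfit glm vcov coef setNames dist hclust
#' @importFrom utils read.csv write.csv write.table read.delim packageVersion
NULL

# Named RNG substreams derived from one top-level seed, so e.g. changing the
# subsampling draw does not perturb the SOM initialization.
.substream_offsets <- c(sim = 101L, som = 202L, subsample = 303L, general = 404L)

substream_seed <- function(seed, name = "general") {
  offset <- .substream_offsets[[name]]
  as.integer((as.numeric(seed) * 7919 + offset) %% (.Machine$integer.max - 1))
}

with_substream <- function(seed, name, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(substream_seed(seed, name))
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a

msg <- function(..., verbose = getOption("cytodiscover.verbose", TRUE)) {
  if (isTRUE(verbose)) message(...)
}
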