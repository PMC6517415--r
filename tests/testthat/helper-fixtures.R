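options(cytodiscover.verbose = FALSE)

# Small deterministic experiment built directly from matrices.
make_bundle <- function(exprs, cell_sample, marker_class = NULL,
                        samples = NULL, state = "arcsinh") {
  exprs <- as.matrix(exprs)
  if (is.null(colnames(exprs)))
    colnames(exprs) <- paste0("m", seq_len(ncol(exprs)))
  if (is.null(marker_class))
    marker_class <- rep("cell_type", ncol(exprs))
  mk <- marker_info(colnames(exprs), marker_class)
  if (is.null(samples)) {
    ids <- unique(as.character(cell_sample))
    samples <- sample_info(ids, group_id = rep(c("g1", "g2"),
                                               length.out = length(ids)))
  }
  cytodiscover:::new_experiment(exprs, cell_sample, mk, samples,
                                transform = list(state = state, cofactor = 5))
}

# A clustered two-condition paired toy: counts matrix with known structure.
toy_counts <- function(counts, sample_ids = NULL) {
  counts <- as.matrix(counts)
  if (is.null(colnames(counts)))
    colnames(counts) <- sample_ids %||% paste0("s", seq_len(ncol(counts)))
  structure(list(counts = counts, lib_sizes = colSums(counts),
                 cluster_ids = seq_len(nrow(counts)),
                 sample_ids = colnames(counts)),
            class = "cluster_counts")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---- independent oracles ---------------------------------------------------

# Gauss-Hermite nodes/weights by Golub-Welsch (eigen decomposition of the
# Jacobi matrix); independent of the package's Laplace machinery.
gh_nodes <- function(k) {
  i <- seq_len(k - 1)
  J <- matrix(0, k, k)
  J[cbind(i, i + 1)] <- J[cbind(i + 1, i)] <- sqrt(i / 2)
  e <- eigen(J, symmetric = TRUE)
  list(x = e$values, w = sqrt(pi) * e$vectors[1, ]^2)
}

# Adaptive Gauss-Hermite marginal log-likelihood for a binomial model with a
# single random intercept (one independent integral per block).
gh_binomial_loglik <- function(beta, sigma, y, n, X, blk, k = 21) {
  gh <- gh_nodes(k)
  eta0 <- drop(X %*% beta)
  ll <- 0
  for (b in levels(blk)) {
    idx <- blk == b
    g <- function(u) sum(dbinom(y[idx], n[idx], plogis(eta0[idx] + u), log = TRUE)) +
      dnorm(u, 0, sigma, log = TRUE)
    m <- optimize(function(u) -g(u), c(-15, 15))$minimum
    h <- 1e-4
    curv <- (g(m + h) - 2 * g(m) + g(m - h)) / h^2
    s <- 1 / sqrt(-curv)
    vals <- vapply(gh$x, function(t) g(m + sqrt(2) * s * t) + t^2, 0)
    ll <- ll + log(sum(gh$w * exp(vals - max(vals)))) + max(vals) +
      log(sqrt(2) * s)
  }
  ll
}

# Run the full DA or DS pipeline on a simulated benchmark; used by the
# power/calibration tests and the acceptance suite.
run_benchmark <- function(mode = c("da", "ds", "null"), method,
                          n_per_group = 5, cells_per_sample = 5000,
                          spike_threshold = 0.01, grid = 10, seed = 1,
                          level = "cell", glmm_test = "wald") {
  mode <- match.arg(mode)
  cfg <- sim_config(n_per_group = n_per_group,
                    cells_per_sample = cells_per_sample,
                    spike_threshold = spike_threshold, seed = seed)
  sim <- switch(mode,
                da = simulate_da_benchmark(cfg),
                ds = suppressWarnings(simulate_ds_benchmark(cfg)),
                null = list(bundle = simulate_null(cfg), truth = NULL))
  b <- arcsinh_transform(sim$bundle)
  m <- som_train(b, som_params(grid, grid, seed = seed))
  a <- som_assign(m, b)
  K <- grid^2
  cnt <- compute_counts(a, b, K)
  med <- if (startsWith(method, "ds")) compute_medians(a, b, K = K) else NULL
  des <- build_design(b$samples, c("group", "block"))
  ctr <- make_contrast(des, c(group_cond2 = 1))
  res <- switch(method,
    "da-nb" = run_da_nb(cnt, des, ctr),
    "da-wlm" = run_da_weighted_lm(cnt, des, ctr),
    "da-glmm" = {
      fml <- build_formula(b$samples, "group", "block", olre = TRUE)
      suppressWarnings(run_da_glmm(cnt, fml, make_contrast(fml, c(group_cond2 = 1)),
                                   test = glmm_test))
    },
    "ds-mod" = run_ds_moderated(med, cnt, des, ctr),
    "ds-lmm" = {
      fml <- build_formula(b$samples, "group", "block")
      run_ds_lmm(med, cnt, fml, make_contrast(fml, c(group_cond2 = 1)))
    },
    stop("unknown method"))
  ev <- if (mode != "null") evaluate_results(res, a, sim$truth, K, level = level)
  list(results = res, assignment = a, truth = sim$truth, eval = ev, K = K,
       bundle = b, counts = cnt, medians = med)
}
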