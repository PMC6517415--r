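test_that("shifted cluster-marker combinations are detected, others are not enriched", {
  bench <- run_benchmark("ds", "ds-mod", n_per_group = 8,
                         cells_per_sample = 2000, grid = 10, seed = 11,
                         level = "cluster")
  r <- bench$results
  shifted <- attr(bench$truth, "shifted_marker")
  lab_cl <- label_clusters(bench$assignment, bench$truth$target_pop, bench$K)
  pos <- lab_cl[r$cluster] & r$marker == shifted
  expect_gt(sum(pos), 3)
  expect_gt(mean(r$p_adj[pos] <= 0.1, na.rm = TRUE), 0.8)
  # non-shifted markers in the same clusters are not enriched
  other <- lab_cl[r$cluster] & r$marker != shifted
  expect_lt(mean(r$p_adj[other] <= 0.1, na.rm = TRUE), 0.1)
  # combinations = retained clusters x state markers, BH joint
  expect_equal(nrow(r), bench$K * 4L)
  kept <- !is.na(r$p_val)
  expect_equal(r$p_adj[kept], bh_adjust(r$p_val[kept]))
})

test_that("the LMM route also detects the shifted combinations on paired data", {
  bench <- run_benchmark("ds", "ds-lmm", n_per_group = 8,
                         cells_per_sample = 2000, grid = 10, seed = 11,
                         level = "cluster")
  expect_gt(bench$eval$at_cutoffs$tpr[3], 0.8)
})

test_that("with equal counts the weights have no effect", {
  set.seed(34)
  K <- 6; S <- 8
  med <- array(rnorm(K * S * 2), c(K, S, 2),
               dimnames = list(1:K, paste0("s", 1:S), c("SM1", "SM2")))
  medians <- structure(list(medians = med,
                            marker_class = c(SM1 = "cell_state", SM2 = "cell_state"),
                            cluster_ids = 1:K, sample_ids = paste0("s", 1:S)),
                       class = "cluster_medians")
  cnt <- toy_counts(matrix(50L, K, S))
  sm <- sample_info(paste0("s", 1:S), rep(c("A", "B"), each = 4))
  X <- build_design(sm, "group")
  ctr <- make_contrast(X, c(group_B = 1))
  r_w <- run_ds_moderated(medians, cnt, X, ctr, weights = TRUE)
  r_nw <- run_ds_moderated(medians, cnt, X, ctr, weights = FALSE)
  expect_equal(r_w$p_val, r_nw$p_val, tolerance = 1e-10)
  expect_equal(r_w$effect, r_nw$effect, tolerance = 1e-10)
})

test_that("moderated and per-combination LM routes agree without squeezing", {
  set.seed(35)
  S <- 16
  sm <- sample_info(paste0("s", 1:S), rep(c("A", "B"), each = 8))
  X <- build_design(sm, "group")
  ctr <- make_contrast(X, c(group_B = 1))
  Y <- matrix(rnorm(30 * S, sd = 0.6), 30, S)
  fits <- weighted_lm_fit(Y, X, NULL, ctr)
  t_cl <- fits$beta / (fits$u * sqrt(fits$s2))
  p_t <- 2 * pt(-abs(t_cl), fits$df)          # classical t (d0 = 0)
  p_z <- vapply(seq_len(30), function(i)
    fit_lmm(Y[i, ], X, list(), ctr)$p_val, 0)  # LM route, t reference
  expect_lt(max(abs(p_t - p_z)), 0.02)
})

test_that("a missing sample reduces the fit's degrees of freedom", {
  set.seed(36)
  S <- 8
  sm <- sample_info(paste0("s", 1:S), rep(c("A", "B"), each = 4))
  X <- build_design(sm, "group")
  ctr <- make_contrast(X, c(group_B = 1))
  y <- rnorm(S); y[3] <- NA
  fits <- weighted_lm_fit(matrix(y, 1), X, NULL, ctr)
  expect_equal(fits$df, S - 1 - 2)
  f <- fit_lmm(y, X, list(), ctr)
  expect_equal(f$df, S - 1 - 2)
})

test_that("results are invariant to cluster and marker ordering", {
  set.seed(37)
  K <- 5; S <- 6
  med <- array(rnorm(K * S * 3), c(K, S, 3),
               dimnames = list(1:K, paste0("s", 1:S), c("SM1", "SM2", "SM3")))
  medians <- structure(list(medians = med,
                            marker_class = setNames(rep("cell_state", 3),
                                                    c("SM1", "SM2", "SM3")),
                            cluster_ids = 1:K, sample_ids = paste0("s", 1:S)),
                       class = "cluster_medians")
  cnt <- toy_counts(matrix(rpois(K * S, 60), K, S))
  sm <- sample_info(paste0("s", 1:S), rep(c("A", "B"), 3))
  X <- build_design(sm, "group")
  ctr <- make_contrast(X, c(group_B = 1))
  r <- run_ds_moderated(medians, cnt, X, ctr)
  med2 <- medians
  med2$medians <- medians$medians[, , c(3, 1, 2)]
  med2$marker_class <- medians$marker_class[c(3, 1, 2)]
  r2 <- run_ds_moderated(med2, cnt, X, ctr)
  key <- function(d) d[order(d$cluster, d$marker), c("effect", "p_val", "p_adj")]
  expect_equal(key(r), key(r2), ignore_attr = TRUE)
})

test_that("the DS effect sign follows the contrast's positive condition", {
  set.seed(38)
  K <- 3; S <- 6
  med <- array(0, c(K, S, 1), dimnames = list(1:K, paste0("s", 1:S), "SM1"))
  med[2, 4:6, 1] <- 1.5  # higher in group B
  med[, , 1] <- med[, , 1] + matrix(rnorm(K * S, 0, 0.01), K, S)
  medians <- structure(list(medians = med, marker_class = c(SM1 = "cell_state"),
                            cluster_ids = 1:K, sample_ids = paste0("s", 1:S)),
                       class = "cluster_medians")
  cnt <- toy_counts(matrix(50L, K, S))
  sm <- sample_info(paste0("s", 1:S), rep(c("A", "B"), each = 3))
  X <- build_design(sm, "group")
  r <- run_ds_moderated(medians, cnt, X, make_contrast(X, c(group_B = 1)))
  expect_gt(r$effect[r$cluster == 2], 1.3)
})
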