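# Small end-to-end DA checks; the full-size benchmark properties live in
# test-acceptance.R.

test_that("identical counts across samples are never significant", {
  cnt <- toy_counts(matrix(40L, 8, 6))
  sm <- sample_info(paste0("s", 1:6), rep(c("A", "B"), each = 3))
  X <- build_design(sm, "group")
  ctr <- make_contrast(X, c(group_B = 1))
  r <- run_da_nb(cnt, X, ctr)
  expect_true(all(r$p_val > 0.999))
  r2 <- run_da_weighted_lm(cnt, X, ctr)
  expect_true(all(r2$p_adj > 0.1))  # nothing significant at any standard cutoff
})

test_that("an intercept-only contrast request is rejected", {
  cnt <- toy_counts(matrix(40L, 8, 4))
  sm <- sample_info(paste0("s", 1:4), rep("A", 4))
  X <- build_design(sm, "group")  # single level: intercept only
  ctr <- setNames(c(1), "(Intercept)")
  expect_error(run_da_weighted_lm(cnt, X, ctr), "no testable coefficient")
})

test_that("block random effects require non-singleton blocks", {
  cnt <- toy_counts(matrix(rpois(40, 50), 10, 4))
  sm <- sample_info(paste0("s", 1:4), rep(c("A", "B"), 2))
  X <- build_design(sm, "group")
  ctr <- make_contrast(X, c(group_B = 1))
  expect_error(run_da_weighted_lm(cnt, X, ctr, block_random = TRUE,
                                  block = factor(1:4)),
               "singleton")
})

test_that("block-as-fixed and block-as-random variants agree on a balanced toy", {
  set.seed(33)
  nb <- 8
  blk <- factor(rep(seq_len(nb), each = 2))
  grp <- rep(c("A", "B"), nb)
  base <- matrix(rpois(30 * nb * 2, 100), 30)
  bump <- exp(rnorm(nb, 0, 0.25))   # shared within-block depth wiggle
  cntm <- round(t(t(base) * rep(bump, each = 2)))
  cntm[1:3, grp == "B"] <- cntm[1:3, grp == "B"] + 60L
  cnt <- toy_counts(cntm)
  sm <- sample_info(paste0("s", seq_len(2 * nb)), grp, block_id = blk)
  Xf <- build_design(sm, c("group", "block"))
  Xr <- build_design(sm, "group")
  ctr_f <- make_contrast(Xf, c(group_B = 1))
  ctr_r <- make_contrast(Xr, c(group_B = 1))
  rf <- run_da_weighted_lm(cnt, Xf, ctr_f)
  rr <- run_da_weighted_lm(cnt, Xr, ctr_r, block_random = TRUE, block = blk)
  expect_true(all(sign(rf$effect[1:3]) == sign(rr$effect[1:3])))
  expect_gt(cor(rank(rf$p_val), rank(rr$p_val)), 0.9)
})

test_that("all three DA routes top-rank the same strongly spiked cluster", {
  bench <- run_benchmark("da", "da-nb", n_per_group = 5,
                         cells_per_sample = 2000, spike_threshold = 0.05,
                         grid = 8, seed = 7)
  top_nb <- which.min(bench$results$p_val)
  r_wlm <- run_da_weighted_lm(bench$counts,
                              build_design(bench$bundle$samples, c("group", "block")),
                              make_contrast(build_design(bench$bundle$samples,
                                                         c("group", "block")),
                                            c(group_cond2 = 1)))
  fml <- build_formula(bench$bundle$samples, "group", "block", olre = TRUE)
  r_glmm <- suppressWarnings(run_da_glmm(bench$counts, fml,
                                         make_contrast(fml, c(group_cond2 = 1)),
                                         test = "lrt"))
  expect_equal(which.min(r_wlm$p_val), top_nb)
  expect_equal(which.min(r_glmm$p_val), top_nb)
  # the top cluster is a true spiked cluster
  labs <- label_clusters(bench$assignment, bench$truth$spike, bench$K)
  expect_true(labs[top_nb])
  # retained cluster sets are identical across methods given the same filter
  expect_equal(r_wlm$filtered, bench$results$filtered)
  expect_equal(r_glmm$filtered, bench$results$filtered)
})

test_that("results tables have one row per cluster and BH spans retained clusters", {
  bench <- run_benchmark("da", "da-nb", n_per_group = 4,
                         cells_per_sample = 1000, spike_threshold = 0.05,
                         grid = 5, seed = 3)
  r <- bench$results
  expect_equal(nrow(r), 25L)
  expect_true(all(is.na(r$p_val[r$filtered])))
  kept <- !r$filtered & !is.na(r$p_val)
  expect_equal(r$p_adj[kept], bh_adjust(r$p_val[kept]))
  expect_true(all(r$p_adj >= r$p_val, na.rm = TRUE))
})
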