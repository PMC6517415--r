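test_that("the DA generator spikes exactly round(theta * n) cells per condition-2 sample", {
  cfg <- sim_config(n_per_group = 3, cells_per_sample = 5000,
                    spike_threshold = 0.01, seed = 2)
  sim <- simulate_da_benchmark(cfg)
  frac <- attr(sim$truth, "spike_fraction")
  cond2 <- sim$bundle$samples$group_id == "cond2"
  expect_equal(as.numeric(frac[cond2]), rep(50 / 5000, 3))
  expect_equal(as.numeric(frac[!cond2]), rep(0, 3))
  # per-sample cell totals are exact
  expect_equal(as.integer(table(sim$bundle$cell_sample)), rep(5000L, 6))
  expect_error(simulate_da_benchmark(sim_config(cells_per_sample = 100,
                                                spike_threshold = 0.001)),
               "increase cells_per_sample")
})

test_that("generation is deterministic given the seed", {
  cfg <- sim_config(n_per_group = 2, cells_per_sample = 500, seed = 9)
  s1 <- simulate_da_benchmark(cfg)
  s2 <- simulate_da_benchmark(cfg)
  expect_identical(s1$bundle$exprs, s2$bundle$exprs)
  expect_identical(s1$truth$spike, s2$truth$spike)
  s3 <- simulate_da_benchmark(sim_config(n_per_group = 2, cells_per_sample = 500,
                                         seed = 10))
  expect_false(identical(s1$bundle$exprs, s3$bundle$exprs))
})

test_that("the DS shift moves only the designated state marker by delta", {
  cfg <- sim_config(n_per_group = 4, cells_per_sample = 5000,
                    state_shift = 1.5, seed = 5)
  sim <- suppressWarnings(simulate_ds_benchmark(cfg))
  b <- arcsinh_transform(sim$bundle)
  shifted <- attr(sim$truth, "shifted_marker")
  cond2 <- as.character(b$cell_sample) %in%
    b$samples$sample_id[b$samples$group_id == "cond2"]
  pop <- sim$truth$target_pop
  d <- mean(b$exprs[pop & cond2, shifted]) - mean(b$exprs[pop & !cond2, shifted])
  expect_equal(d, 1.5, tolerance = 0.05)
  # cell type markers are condition-blind: identical to the matched null
  null_sim <- cytodiscover:::sim_generate(cfg, "null")
  expect_identical(sim$bundle$exprs[, 1:10], null_sim$bundle$exprs[, 1:10])
  expect_false(identical(sim$bundle$exprs[, shifted],
                         null_sim$bundle$exprs[, shifted]))
  # spike flags exist only in condition-2 samples
  expect_true(all(!sim$truth$spike[!cond2]))
})

test_that("a zero state shift yields a valid null dataset", {
  cfg <- sim_config(n_per_group = 3, cells_per_sample = 800, state_shift = 0,
                    seed = 6)
  sim <- suppressWarnings(simulate_ds_benchmark(cfg))
  b <- arcsinh_transform(sim$bundle)
  shifted <- attr(sim$truth, "shifted_marker")
  cond2 <- as.character(b$cell_sample) %in%
    b$samples$sample_id[b$samples$group_id == "cond2"]
  pop <- sim$truth$target_pop
  d <- mean(b$exprs[pop & cond2, shifted]) - mean(b$exprs[pop & !cond2, shifted])
  expect_lt(abs(d), 0.15)
})

test_that("the null generator is label-exchangeable and proportion-consistent", {
  cfg <- sim_config(n_per_group = 3, cells_per_sample = 2000, seed = 8)
  b1 <- simulate_null(cfg)
  b2 <- simulate_null(cfg)
  # same seed, labels carried in metadata only: identical cells
  expect_identical(b1$exprs, b2$exprs)
  # realized pooled proportions track the Dirichlet mixture draw
  sim <- cytodiscover:::sim_generate(cfg, "null")
  realized <- as.numeric(table(factor(sim$truth$population, 1:8)) /
                           nrow(sim$truth))
  base <- attr(sim$truth, "base_proportions")
  expect_equal(length(realized), 8L)
  expect_lt(max(abs(realized - base)), 0.05)
  expect_gt(cor(realized, base), 0.95)
})

test_that("vanishing signal strength collapses the spike onto a base population", {
  cfg1 <- sim_config(n_per_group = 2, cells_per_sample = 1000,
                     spike_threshold = 0.05, signal_strength = 1, seed = 3)
  cfg0 <- sim_config(n_per_group = 2, cells_per_sample = 1000,
                     spike_threshold = 0.05, signal_strength = 0.01, seed = 3)
  s1 <- simulate_da_benchmark(cfg1)
  s0 <- simulate_da_benchmark(cfg0)
  b1 <- arcsinh_transform(s1$bundle); b0 <- arcsinh_transform(s0$bundle)
  base_mean <- colMeans(b0$exprs[!s0$truth$spike, 1:10])
  spike1 <- colMeans(b1$exprs[s1$truth$spike, 1:10])
  spike0 <- colMeans(b0$exprs[s0$truth$spike, 1:10])
  # the weak-signal spike phenotype sits much closer to the base data
  d1 <- sqrt(sum((spike1 - base_mean)^2))
  d0 <- sqrt(sum((spike0 - base_mean)^2))
  expect_lt(d0, d1)
})
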