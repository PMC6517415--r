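test_that("intercept-only binomial model recovers the pooled proportion", {
  X <- matrix(1, 2, 1, dimnames = list(NULL, "(Intercept)"))
  f <- fit_binomial_glmm(c(3, 7), c(10, 10), X, list(), contrast = 1)
  expect_equal(f$beta, qlogis(0.5), tolerance = 1e-6)
})

test_that("equal group proportions give a null contrast", {
  X <- cbind("(Intercept)" = 1, grp = rep(0:1, each = 3))
  f <- fit_binomial_glmm(c(30, 30, 30, 30, 30, 30), rep(100L, 6), X, list(),
                         contrast = c(0, 1))
  expect_equal(f$beta, 0, tolerance = 1e-6)
  expect_gt(f$p_val, 0.99)
})

test_that("Laplace likelihood and estimates match quadrature and glmer oracles", {
  set.seed(3)
  S <- 6
  X <- cbind("(Intercept)" = 1, grp = rep(0:1, 3))
  blk <- factor(rep(1:3, each = 2))
  u <- rnorm(3, 0, 0.8)
  n <- rep(500L, S)
  y <- rbinom(S, n, plogis(drop(X %*% c(-1, 0.7)) + u[blk]))
  fit <- fit_binomial_glmm(y, n, X, list(block = blk), c(0, 1))
  # adaptive 21-node Gauss-Hermite at the fitted parameters
  sig <- fit$sigma[["block"]]
  pf <- cytodiscover:::pirls_binomial(y, n, X, list(model.matrix(~ 0 + blk)),
                                      sig^2)
  ll_gh <- gh_binomial_loglik(pf$beta, sig, y, n, X, blk)
  expect_lt(abs(fit$loglik - ll_gh), 0.05)
  gm <- suppressMessages(lme4::glmer(cbind(y, n - y) ~ X[, 2] + (1 | blk),
                                     family = binomial, nAGQ = 21))
  expect_lt(abs(fit$beta - unname(lme4::fixef(gm)[2])), 0.02)
})

test_that("a vanishing OLRE variance reduces to the binomial GLM", {
  set.seed(5)
  S <- 10
  X <- cbind("(Intercept)" = 1, grp = rep(0:1, each = 5))
  n <- rep(1000L, S)
  y <- rbinom(S, n, plogis(-1 + 0.5 * X[, 2]))   # no overdispersion
  f <- fit_binomial_glmm(y, n, X, list(olre = factor(seq_len(S))), c(0, 1))
  g <- glm(cbind(y, n - y) ~ X[, 2], family = binomial)
  expect_lt(abs(f$beta - unname(coef(g)[2])), 1e-4)
  expect_lt(abs(f$p_val - summary(g)$coefficients[2, 4]), 1e-4)
})

test_that("OLRE terms restore calibration on overdispersed binomial nulls", {
  set.seed(30)
  S <- 10
  X <- cbind("(Intercept)" = 1, grp = rep(0:1, each = 5))
  olre <- factor(seq_len(S))
  n <- rep(2000L, S)
  p_with <- p_without <- numeric(150)
  for (i in seq_len(150)) {
    pr <- plogis(qlogis(0.05) + rnorm(S, 0, 0.4))   # extra-binomial noise
    y <- rbinom(S, n, pr)
    p_with[i] <- fit_binomial_glmm(y, n, X, list(olre = olre), c(0, 1))$p_val
    p_without[i] <- fit_binomial_glmm(y, n, X, list(), c(0, 1))$p_val
  }
  expect_gt(mean(p_without < 0.05, na.rm = TRUE), 0.3)  # anti-conservative
  expect_lt(mean(p_with < 0.05, na.rm = TRUE), 0.12)
  expect_gt(pvalue_uniformity(p_with)$p_value, 0.01)
})

test_that("zero-total samples are dropped from the cluster's model", {
  X <- cbind("(Intercept)" = 1, grp = rep(0:1, each = 3))
  y <- c(10, 12, 0, 40, 38, 0)
  n <- c(100L, 100L, 0L, 100L, 100L, 0L)
  f <- fit_binomial_glmm(y, n, X, list(), c(0, 1))
  g <- glm(cbind(y[n > 0], (n - y)[n > 0]) ~ X[n > 0, 2], family = binomial)
  expect_equal(f$beta, unname(coef(g)[2]), tolerance = 1e-6)
})

test_that("the linear mixed model reduces to weighted least squares without random terms", {
  set.seed(31)
  S <- 8
  X <- cbind("(Intercept)" = 1, grp = rep(0:1, each = 4))
  y <- rnorm(S) + 0.5 * X[, 2]
  w <- rexp(S) + 0.5
  f <- fit_lmm(y, X, list(), c(0, 1), weights = w)
  ref <- weighted_lm_fit(matrix(y, 1), X, matrix(w, 1), c(0, 1))
  expect_equal(f$beta, ref$beta, tolerance = 1e-10)
  expect_equal(f$se, ref$u * sqrt(ref$s2), tolerance = 1e-10)
  expect_equal(f$p_val, 2 * pt(-abs(ref$beta / (ref$u * sqrt(ref$s2))), ref$df),
               tolerance = 1e-10)
})

test_that("balanced paired data matches the paired closed form", {
  set.seed(4)
  nb <- 6
  blk <- factor(rep(1:nb, each = 2))
  grp <- rep(0:1, nb)
  y <- 2 + rnorm(nb, 0, 2)[blk] + 0.9 * grp + rnorm(2 * nb, 0, 0.5)
  X <- cbind("(Intercept)" = 1, grp = grp)
  f <- fit_lmm(y, X, list(block = blk), c(0, 1))
  d <- y[grp == 1] - y[grp == 0]
  expect_equal(f$beta, mean(d), tolerance = 1e-6)
  expect_equal(f$se, sd(d) / sqrt(nb), tolerance = 1e-6)
})

test_that("a constant response returns effect 0 with p = 1", {
  X <- cbind("(Intercept)" = 1, grp = rep(0:1, each = 3))
  f <- fit_lmm(rep(2.5, 6), X, list(), c(0, 1))
  expect_equal(f$beta, 0)
  expect_equal(f$p_val, 1)
})

test_that("BH adjustment follows the step-up rule and handles missing values", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  p <- c(0.01, NA, 0.04)
  out <- bh_adjust(p)
  expect_true(is.na(out[2]))
  expect_equal(out[c(1, 3)], p.adjust(c(0.01, 0.04), "BH"))
})
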