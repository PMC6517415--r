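test_that("the posterior variance is the stated convex combination", {
  expect_equal(squeeze_posterior(3, 4, d0 = 4, s02 = 1), 2)
  expect_equal(squeeze_posterior(c(3, 7), 4, d0 = Inf, s02 = 1.5), c(1.5, 1.5))
})

test_that("prior estimation recovers generating d0 and s0^2", {
  set.seed(21)
  s2 <- 2 * rf(2000, 4, 10)   # s^2 ~ s0^2 * F(d, d0), d = 4, d0 = 10, s0^2 = 2
  sq <- squeeze_var(s2, 4)
  expect_gt(sq$d0, 7); expect_lt(sq$d0, 14)
  expect_gt(sq$s02, 1.8); expect_lt(sq$s02, 2.2)
  # every squeezed value lies between the unit's variance and the prior
  between <- (sq$s2_post - s2) * (sq$s2_post - sq$s02) <= 1e-12
  expect_true(all(between))
})

test_that("variance squeezing matches the reference implementation", {
  set.seed(22)
  s2 <- 1.3 * rf(800, 6, 12)
  sq <- squeeze_var(s2, 6)
  lq <- limma::squeezeVar(s2, 6)
  expect_equal(sq$d0, lq$df.prior, tolerance = 1e-6)
  expect_equal(sq$s02, lq$var.prior, tolerance = 1e-6)
  expect_equal(sq$s2_post, lq$var.post, tolerance = 1e-8)
})

test_that("fewer than 3 units falls back to an infinite prior with a warning", {
  expect_warning(sq <- squeeze_var(c(1, 2), 4), "fewer than 3")
  expect_equal(sq$d0, Inf)
  expect_equal(sq$s2_post, rep(1.5, 2))
})

test_that("homoscedastic data gives near-uniform precision weights", {
  set.seed(23)
  # counts whose log2 values have constant variance across a wide mean range
  mu <- runif(400, 5, 12)
  y <- matrix(mu + rnorm(400 * 8, 0, 0.1), 400, 8)
  cnt <- round(2^y)
  X <- cbind(1, rep(0:1, each = 4))
  vw <- voom_weights(cnt, X, colSums(cnt))
  expect_true(all(is.finite(vw$weights)) && all(vw$weights > 0))
  mean_w <- mean(vw$weights)
  expect_lt(max(abs(vw$weights / mean_w - 1)), 0.2)
})

test_that("weighted least squares matches lm() oracles", {
  set.seed(24)
  S <- 8
  X <- cbind("(Intercept)" = 1, grp = rep(0:1, each = 4))
  Y <- matrix(rnorm(50 * S), 50, S)
  ctr <- c(0, 1)
  fits <- weighted_lm_fit(Y, X, NULL, ctr)
  for (i in c(1, 17, 50)) {
    ref <- lm(Y[i, ] ~ X[, 2])
    expect_equal(fits$beta[i], unname(coef(ref)[2]), tolerance = 1e-10)
    expect_equal(fits$s2[i], summary(ref)$sigma^2, tolerance = 1e-10)
    expect_equal(fits$u[i] * sqrt(fits$s2[i]),
                 summary(ref)$coefficients[2, 2], tolerance = 1e-10)
  }
  # perfect fit: response equal to the contrast column
  fits0 <- weighted_lm_fit(matrix(X[, 2], 1), X, NULL, ctr)
  expect_equal(fits0$beta, 1, tolerance = 1e-12)
  expect_equal(fits0$s2, 0, tolerance = 1e-12)
})

test_that("duplicating samples at half weight reproduces the estimate", {
  set.seed(25)
  X <- cbind(1, rep(0:1, each = 3))
  y <- rnorm(6)
  f1 <- weighted_lm_fit(matrix(y, 1), X, matrix(1, 1, 6), c(0, 1))
  Xd <- rbind(X, X)
  f2 <- weighted_lm_fit(matrix(c(y, y), 1), Xd, matrix(0.5, 1, 12), c(0, 1))
  expect_equal(f1$beta, f2$beta, tolerance = 1e-10)
})

test_that("doubling all weights leaves moderated t statistics unchanged", {
  set.seed(26)
  S <- 8
  X <- cbind(1, rep(0:1, each = 4))
  Y <- matrix(rnorm(100 * S), 100, S)
  W <- matrix(rexp(100 * S) + 0.5, 100, S)
  t1 <- moderated_test(f1 <- weighted_lm_fit(Y, X, W, c(0, 1)),
                       squeeze_var(f1$s2, f1$df))
  t2 <- moderated_test(f2 <- weighted_lm_fit(Y, X, 2 * W, c(0, 1)),
                       squeeze_var(f2$s2, f2$df))
  expect_equal(t1$t, t2$t, tolerance = 1e-9)
})

test_that("moderated t matches a hand computation on a 3 vs 3 toy", {
  y <- c(1.0, 1.4, 0.8, 2.1, 2.6, 2.2)
  X <- cbind(1, rep(0:1, each = 3))
  w <- c(1, 2, 1, 1, 2, 1)
  # hand WLS: solve the normal equations directly
  XtW <- t(X * w)
  beta_hand <- solve(XtW %*% X, XtW %*% y)
  resid <- y - drop(X %*% beta_hand)
  s2_hand <- sum(w * resid^2) / (6 - 2)
  u_hand <- sqrt(solve(XtW %*% X)[2, 2])
  d0 <- 4; s02 <- 0.05
  s2_post <- (d0 * s02 + 4 * s2_hand) / (d0 + 4)
  t_hand <- beta_hand[2] / (u_hand * sqrt(s2_post))
  p_hand <- 2 * pt(-abs(t_hand), df = 4 + d0)
  fits <- weighted_lm_fit(matrix(y, 1), X, matrix(w, 1), c(0, 1))
  prior <- list(d0 = d0, s02 = s02,
                s2_post = squeeze_posterior(fits$s2, fits$df, d0, s02))
  mt <- moderated_test(fits, prior)
  expect_equal(mt$t, unname(t_hand), tolerance = 1e-8)
  expect_equal(mt$p_val, unname(p_hand), tolerance = 1e-8)
})

test_that("d0 = 0 recovers the classical t statistic", {
  set.seed(27)
  X <- cbind(1, rep(0:1, each = 4))
  Y <- matrix(rnorm(20 * 8), 20, 8)
  fits <- weighted_lm_fit(Y, X, NULL, c(0, 1))
  mt <- moderated_test(fits, list(d0 = 0, s02 = 1, s2_post = fits$s2))
  expect_equal(mt$t, fits$beta / (fits$u * sqrt(fits$s2)), tolerance = 1e-10)
})

test_that("moderated p-values are approximately uniform on null normal data", {
  set.seed(28)
  X <- cbind(1, rep(0:1, each = 4))
  Y <- matrix(rnorm(2000 * 8), 2000, 8)
  fits <- weighted_lm_fit(Y, X, NULL, c(0, 1))
  mt <- moderated_test(fits, squeeze_var(fits$s2, fits$df))
  expect_gt(pvalue_uniformity(mt$p_val)$p_value, 0.01)
})

test_that("the consensus correlation recovers the generating block correlation", {
  set.seed(29)
  S <- 12
  blk <- factor(rep(1:6, each = 2))
  X <- cbind(1, rep(0:1, 6))
  # rho = 0: independent samples
  Y0 <- matrix(rnorm(300 * S), 300, S)
  rho0 <- consensus_correlation(Y0, X, blk)
  expect_lt(abs(rho0), 0.1)
  # block SD = residual SD so within-block correlation is 0.5
  Yb <- t(replicate(500, rnorm(6)[blk] + rnorm(S)))
  rho5 <- consensus_correlation(Yb, X, blk)
  expect_gt(rho5, 0.35); expect_lt(rho5, 0.65)
  # a single unit returns that unit's estimate
  r1 <- consensus_correlation(Yb[1, , drop = FALSE], X, blk)
  expect_equal(r1, tanh(atanh(cytodiscover:::reml_rho_one(Yb[1, ], X, rep(1, S), blk))))
  expect_error(consensus_correlation(Y0, X, factor(1:S)), "singleton")
})
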