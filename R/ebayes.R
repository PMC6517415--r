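# Empirical Bayes moderation kernels: variance squeezing by F-distribution
# moment matching on log sample variances, mean-variance precision weights
# for count data, weighted/generalized least squares fits, moderated t
# statistics, and the consensus within-block correlation used for random
# effects in the linear-model route.

# Solve trigamma(y) = x for y > 0 (Newton on a convex decreasing function).
trigamma_inverse <- function(x) {
  if (!is.finite(x) || x <= 0) return(Inf)
  if (x > 1e7) return(1 / sqrt(x))
  if (x < 1e-6) return(1 / x)
  y <- 0.5 + 1 / x
  for (i in 1:75) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, deriv = 2L)
    y <- y + dif
    if (abs(dif / y) < 1e-10) break
  }
  y
}

#' Posterior (squeezed) variance
#'
#' Convex combination of a unit's sample variance and the prior:
#' `(d0 * s0^2 + d * s^2) / (d0 + d)`; `d0 = Inf` returns the prior.
#'
#' @param s2 sample variances.
#' @param df residual degrees of freedom per unit.
#' @param d0 prior degrees of freedom (possibly `Inf`).
#' @param s02 prior variance (scalar, or per-unit when a trend is used).
#' @return vector of posterior variances.
#' @export
squeeze_posterior <- function(s2, df, d0, s02) {
  if (is.infinite(d0)) return(rep_len(s02, length(s2)))
  (d0 * s02 + df * s2) / (d0 + df)
}

#' Estimate an empirical Bayes variance prior and squeeze variances
#'
#' Models the per-unit sample variances as scaled F draws around a common
#' prior `s0^2` with `d0` prior degrees of freedom, estimated by matching the
#' first two moments of `log s^2` (digamma/trigamma equations, solved by
#' Newton inversion of the trigamma function). With `trend = TRUE` the prior
#' becomes a LOWESS curve (span 0.5) of `log s^2` against the covariate
#' (typically average log-abundance or average median expression), and `d0`
#' is estimated from the residuals around the curve. Posterior variances are
#' the usual convex combination, so every squeezed value lies between the
#' unit's variance and the prior.
#'
#' @param s2 per-unit sample variances (>= 0).
#' @param df residual degrees of freedom (scalar or per-unit, >= 1).
#' @param covariate optional per-unit trend covariate.
#' @param trend fit a mean-variance trend prior instead of a constant prior.
#' @return list with `d0`, `s02` (scalar or per-unit), `s2_post`.
#' @export
squeeze_var <- function(s2, df, covariate = NULL, trend = FALSE) {
  n <- length(s2)
  df <- rep_len(df, n)
  stopifnot(all(df >= 1), all(s2 >= 0, na.rm = TRUE))
  if (n < 3L) {
    warning("fewer than 3 units: using an infinite prior (no squeezing spread)")
    s02 <- mean(s2, na.rm = TRUE)
    return(list(d0 = Inf, s02 = s02, s2_post = rep(s02, n)))
  }
  z <- log(pmax(s2, 1e-12))
  e <- z - digamma(df / 2) + log(df / 2)
  if (trend && !is.null(covariate)) {
    lo <- lowess(covariate, e, f = 0.5)
    ehat <- approx(lo$x, lo$y, xout = covariate, rule = 2, ties = "ordered")$y
  } else {
    ehat <- rep(mean(e), n)
  }
  resid <- e - ehat
  evar <- sum(resid^2) / (n - 1) - mean(trigamma(df / 2))
  if (is.finite(evar) && evar > 0) {
    d0 <- 2 * trigamma_inverse(evar)
    s02 <- exp(ehat + digamma(d0 / 2) - log(d0 / 2))
  } else {
    d0 <- Inf
    s02 <- exp(ehat)
  }
  if (!trend) s02 <- s02[1]
  list(d0 = d0, s02 = s02, s2_post = squeeze_posterior(s2, df, d0, s02))
}

#' Mean-variance precision weights for count data
#'
#' Cluster cell counts are heteroscedastic on the log-CPM scale. This
#' estimates the mean-variance trend (LOWESS, span 0.5, of the square root
#' of residual standard deviations against average log2 counts from
#' per-cluster linear fits) and converts each observation's fitted log-count
#' into a precision weight `predicted_sqrt_sd^(-4)`, with linear
#' interpolation along the trend and constant extrapolation beyond its range.
#'
#' @param counts K x S matrix of retained cluster counts (or
#'   `cluster_counts`).
#' @param design fixed-effects design matrix.
#' @param eff_lib_sizes effective library sizes (library size x TMM factor).
#' @return list with `y` (log2-CPM matrix), `weights` (K x S, positive), and
#'   the `trend` curve.
#' @export
voom_weights <- function(counts, design, eff_lib_sizes = NULL) {
  if (inherits(counts, "cluster_counts")) {
    eff_lib_sizes <- eff_lib_sizes %||% counts$lib_sizes
    counts <- counts$counts
  }
  K <- nrow(counts); S <- ncol(counts); P <- ncol(design)
  if (K < 2L) stop("precision-weight trend needs at least 2 clusters")
  if (K < 10L) warning("fewer than 10 clusters: mean-variance trend may be unstable")
  y <- log_cpm(counts, eff_lib_sizes)
  fit <- stats::lm.fit(design, t(y))
  sigma <- sqrt(colSums(as.matrix(fit$residuals)^2) / (S - P))
  sx <- rowMeans(y) + mean(log2(eff_lib_sizes + 1)) - log2(1e6)
  sy <- sqrt(sigma)
  l <- lowess(sx, sy, f = 0.5)
  fitted_cpm <- t(design %*% fit$coefficients)           # K x S
  fitted_logcount <- fitted_cpm + rep(log2(eff_lib_sizes + 1), each = K) - log2(1e6)
  pred <- approx(l$x, l$y, xout = as.vector(fitted_logcount), rule = 2,
                 ties = "ordered")$y
  w <- matrix(pmax(pred, 1e-6)^(-4), K, S, dimnames = dimnames(counts))
  list(y = y, weights = w, trend = list(x = l$x, y = l$y))
}

# When missing responses drop samples, fixed-effect columns can become
# aliased (e.g. a block dummy whose samples are all gone). Drop such columns
# provided the contrast does not load on them; otherwise the unit is not
# estimable.
drop_aliased <- function(X, contrast) {
  qx <- qr(X)
  if (qx$rank == ncol(X))
    return(list(X = X, contrast = contrast, rank = qx$rank, ok = TRUE))
  keep <- sort(qx$pivot[seq_len(qx$rank)])
  drop <- setdiff(seq_len(ncol(X)), keep)
  if (any(contrast[drop] != 0))
    return(list(ok = FALSE))
  list(X = X[, keep, drop = FALSE], contrast = contrast[keep],
       rank = qx$rank, ok = TRUE)
}

# Exchangeable within-block correlation matrix scaled by precision weights:
# Sigma = D R D with D = diag(1/sqrt(w)), R[i,j] = rho for same-block pairs.
block_sigma <- function(w, block, rho) {
  R <- outer(block, block, "==") * rho
  diag(R) <- 1
  d <- 1 / sqrt(w)
  R * tcrossprod(d)
}

#' Weighted (or generalized) least squares fits per unit
#'
#' Fits each row of `Y` against the design with per-observation precision
#' weights; when a block factor and consensus correlation are supplied the
#' fit is generalized least squares with block-exchangeable correlation
#' (whitening by the Cholesky factor). Missing responses drop those samples
#' for that unit only. Returns the contrast estimate, its unscaled standard
#' error `u = sqrt(c' (X'WX)^-1 c)`, the residual variance and degrees of
#' freedom; units with no residual degrees of freedom are flagged.
#'
#' @param Y units x samples response matrix (NA allowed).
#' @param design fixed-effects design matrix.
#' @param weights units x samples positive weights (or NULL for unweighted).
#' @param contrast contrast vector.
#' @param block optional per-sample block factor (with `correlation`).
#' @param correlation optional consensus within-block correlation.
#' @return data.frame with `beta`, `u`, `s2`, `df`, `amean`, `ok`.
#' @export
weighted_lm_fit <- function(Y, design, weights = NULL, contrast,
                            block = NULL, correlation = NULL) {
  Y <- as.matrix(Y)
  nunit <- nrow(Y); S <- ncol(Y); P <- ncol(design)
  if (!is.null(weights)) {
    weights <- as.matrix(weights)
    stopifnot(dim(weights) == dim(Y))
  }
  use_gls <- !is.null(block) && !is.null(correlation) && abs(correlation) > 1e-8
  out <- data.frame(beta = rep(NA_real_, nunit), u = NA_real_, s2 = NA_real_,
                    df = NA_real_, amean = NA_real_, ok = FALSE)
  rownames(out) <- rownames(Y)
  for (i in seq_len(nunit)) {
    y <- Y[i, ]
    w <- if (is.null(weights)) rep(1, S) else weights[i, ]
    keep <- is.finite(y) & is.finite(w) & w > 0
    n <- sum(keep)
    if (n <= P) next
    yk <- y[keep]; Xk <- design[keep, , drop = FALSE]; wk <- w[keep]
    da <- drop_aliased(Xk, contrast)
    if (!da$ok) next
    Xk <- da$X; ctr <- da$contrast
    if (n <= ncol(Xk)) next
    if (use_gls) {
      Sig <- block_sigma(wk, as.character(block)[keep], correlation)
      U <- chol(Sig)
      yt <- forwardsolve(t(U), yk)
      Xt <- forwardsolve(t(U), Xk)
      fit <- stats::lm.fit(Xt, yt)
      xtx_inv <- chol2inv(chol(crossprod(Xt)))
    } else {
      fit <- lm.wfit(Xk, yk, wk)
      xtx_inv <- chol2inv(chol(crossprod(Xk * sqrt(wk))))
    }
    rss <- sum(fit$residuals^2 * (if (use_gls) 1 else wk))
    out$beta[i] <- sum(ctr * fit$coefficients)
    out$u[i] <- sqrt(drop(t(ctr) %*% xtx_inv %*% ctr))
    out$df[i] <- n - ncol(Xk)
    out$s2[i] <- rss / (n - ncol(Xk))
    out$amean[i] <- mean(yk)
    out$ok[i] <- TRUE
  }
  out
}

#' Moderated t tests
#'
#' The ordinary t statistic with the residual variance replaced by its
#' squeezed (posterior) value; degrees of freedom are augmented by the prior
#' degrees of freedom (`d0 = 0` recovers the classical t, `d0 = Inf` is
#' capped at 1e6).
#'
#' @param fits output of [weighted_lm_fit()].
#' @param prior output of [squeeze_var()] on the same fits.
#' @return data.frame with `t`, `df_total`, `p_val`.
#' @export
moderated_test <- function(fits, prior) {
  tstat <- fits$beta / (fits$u * sqrt(prior$s2_post))
  df_total <- pmin(fits$df + prior$d0, 1e6)
  p <- 2 * pt(-abs(tstat), df = df_total)
  data.frame(t = tstat, df_total = df_total, p_val = p)
}

# REML estimate of the within-block correlation for a single unit.
reml_rho_one <- function(y, X, w, block, interval = c(-0.9, 0.99)) {
  keep <- is.finite(y) & is.finite(w) & w > 0
  y <- y[keep]; X <- X[keep, , drop = FALSE]; w <- w[keep]
  block <- as.character(block)[keep]
  n <- length(y); P <- ncol(X)
  if (n <= P + 1L) return(NA_real_)
  crit <- function(rho) {
    Sig <- block_sigma(w, block, rho)
    U <- tryCatch(chol(Sig), error = function(e) NULL)
    if (is.null(U)) return(-1e10)
    yt <- forwardsolve(t(U), y)
    Xt <- forwardsolve(t(U), X)
    fit <- stats::lm.fit(Xt, yt)
    rss <- sum(fit$residuals^2)
    ld_sig <- 2 * sum(log(diag(U)))
    xtx <- crossprod(Xt)
    ld_x <- determinant(xtx, logarithm = TRUE)$modulus
    -0.5 * ((n - P) * log(rss / (n - P)) + ld_sig + as.numeric(ld_x))
  }
  optimise(crit, interval = interval, maximum = TRUE, tol = 1e-5)$maximum
}

#' Consensus within-block correlation
#'
#' Per-unit REML estimates of the within-block correlation of a single
#' random-intercept model, combined on the Fisher z scale by a 15% trimmed
#' mean. Downstream fits use generalized least squares with this common
#' block-exchangeable correlation. All-singleton blocks (no repeated
#' measures) are an error: use fixed-effect blocks instead.
#'
#' @param Y units x samples response matrix.
#' @param design fixed-effects design matrix.
#' @param block per-sample block factor.
#' @param weights optional units x samples precision weights.
#' @return consensus correlation (scalar).
#' @export
consensus_correlation <- function(Y, design, block, weights = NULL) {
  block <- factor(block)
  if (all(table(block) < 2L))
    stop("all blocks are singletons; use fixed-effect blocks instead")
  Y <- as.matrix(Y)
  rhos <- vapply(seq_len(nrow(Y)), function(i) {
    w <- if (is.null(weights)) rep(1, ncol(Y)) else weights[i, ]
    reml_rho_one(Y[i, ], design, w, block)
  }, numeric(1))
  rhos <- rhos[is.finite(rhos)]
  if (!length(rhos)) stop("no unit yielded a correlation estimate")
  tanh(mean(atanh(pmin(pmax(rhos, -0.999), 0.999)), trim = 0.15))
}
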