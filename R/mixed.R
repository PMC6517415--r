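# Mixed-model kernels: a binomial GLMM with Laplace-approximated maximum
# likelihood (penalized IRLS inner loop, direct optimization of the variance
# components) used for count-based DA with observation-level random effects,
# and a REML linear mixed model (via lme4) for per-cluster-marker DS fits.

# Penalized IRLS for fixed variance components. X: S x P, Zs: list of
# indicator matrices, sig2: per-term random-intercept variances.
pirls_binomial <- function(y, n, X, Zs, sig2, tol = 1e-6, maxit = 50L) {
  P <- ncol(X)
  qs <- vapply(Zs, ncol, 1L)
  Z <- if (length(Zs)) do.call(cbind, Zs) else matrix(0, length(y), 0L)
  A <- cbind(X, Z)
  pen <- c(rep(0, P), rep(1 / sig2, qs))
  theta <- rep(0, ncol(A))
  # intercept start at pooled proportion
  if (all(X[, 1] == 1)) theta[1] <- qlogis(min(max(sum(y) / sum(n), 1e-6), 1 - 1e-6))
  ok <- FALSE
  for (it in seq_len(maxit)) {
    eta <- drop(A %*% theta)
    p <- plogis(eta)
    W <- pmax(n * p * (1 - p), 1e-10)
    zw <- eta + (y - n * p) / W
    M <- crossprod(A * sqrt(W))
    diag(M) <- diag(M) + pen
    theta_new <- tryCatch(drop(solve(M, crossprod(A, W * zw))),
                          error = function(e) NULL)
    if (is.null(theta_new)) return(NULL)
    delta <- max(abs(theta_new - theta))
    theta <- theta_new
    if (delta < tol) { ok <- TRUE; break }
  }
  eta <- drop(A %*% theta)
  p <- plogis(eta)
  W <- pmax(n * p * (1 - p), 1e-10)
  list(beta = theta[seq_len(P)],
       u = theta[-seq_len(P)],
       eta = eta, W = W, X = X, Z = Z, pen = pen, converged = ok)
}

# Laplace log-likelihood at the joint mode, written as
# l(y|u_hat) - u'Sigma^{-1}u/2 - log|Sigma Z'WZ + I|/2 so that sigma -> 0
# smoothly recovers the plain GLM likelihood.
laplace_loglik <- function(fit, y, n, sig2, qs) {
  ll <- sum(dbinom(y, n, plogis(fit$eta), log = TRUE))
  if (length(fit$u)) {
    siginv <- rep(1 / sig2, qs)
    sig <- rep(sig2, qs)
    ztwz <- crossprod(fit$Z * sqrt(fit$W))
    Mmat <- ztwz * sig + diag(length(fit$u))  # Sigma Z'WZ + I (Sigma diagonal)
    ld <- determinant(Mmat, logarithm = TRUE)$modulus
    ll <- ll - 0.5 * sum(fit$u^2 * siginv) - 0.5 * as.numeric(ld)
  }
  ll
}

#' Binomial GLMM with Laplace-approximated maximum likelihood
#'
#' Logit-link binomial mixed model for cluster counts out of per-sample
#' totals, with random intercepts for blocking factors and/or per-sample
#' observation-level random effects (OLRE) absorbing extra-binomial
#' overdispersion. For fixed variance components the joint mode of fixed and
#' random effects is found by penalized IRLS; the variance components
#' maximize the Laplace-approximated marginal likelihood (direct search over
#' log standard deviations). The contrast is tested with a Wald z statistic
#' by default; a likelihood-ratio test against the null-rotated design is
#' available.
#'
#' @param successes per-sample cluster counts.
#' @param totals per-sample totals (samples with 0 total are dropped).
#' @param design fixed-effects design matrix.
#' @param random named list of per-sample factors, each giving one
#'   random-intercept term (e.g. `list(block = ..., olre = ...)`).
#' @param contrast contrast vector.
#' @param test `"wald"` or `"lrt"`.
#' @return list with `beta` (contrast estimate on the logit scale), `se`,
#'   `stat`, `p_val`, `sigma` (random-intercept SDs), `loglik`, `ok`.
#' @export
fit_binomial_glmm <- function(successes, totals, design, random = list(),
                              contrast, test = c("wald", "lrt")) {
  test <- match.arg(test)
  stopifnot(length(successes) == length(totals),
            all(successes >= 0), all(successes <= totals))
  keep <- totals > 0
  y <- successes[keep]; n <- totals[keep]
  X <- design[keep, , drop = FALSE]
  Zs <- lapply(random, function(f) {
    f <- droplevels(factor(f)[keep])
    stats::model.matrix(~ 0 + f)
  })
  qs <- vapply(Zs, ncol, 1L)
  bad <- list(beta = NA_real_, se = NA_real_, stat = NA_real_, p_val = NA_real_,
              sigma = setNames(rep(NA_real_, length(Zs)), names(Zs)),
              loglik = NA_real_, ok = FALSE)

  fit_at <- function(logsd, Xuse) {
    sig2 <- exp(2 * logsd)
    fit <- pirls_binomial(y, n, Xuse, Zs, sig2)
    if (is.null(fit)) return(NULL)
    list(fit = fit, ll = laplace_loglik(fit, y, n, sig2, qs))
  }

  optimize_model <- function(Xuse) {
    if (length(Zs) == 0L) {
      f <- fit_at(numeric(0), Xuse)
      return(list(logsd = numeric(0), res = f))
    }
    obj <- function(logsd) {
      f <- fit_at(logsd, Xuse)
      if (is.null(f) || !is.finite(f$ll)) 1e10 else -f$ll
    }
    if (length(Zs) == 1L) {
      op <- optimise(obj, interval = c(-6, 3), tol = 1e-6)
      logsd <- op$minimum
    } else {
      op <- optim(rep(-1, length(Zs)), obj, method = "Nelder-Mead",
                  control = list(reltol = 1e-10, maxit = 500L))
      logsd <- pmin(pmax(op$par, -6), 3)
    }
    list(logsd = logsd, res = fit_at(logsd, Xuse))
  }

  full <- optimize_model(X)
  if (is.null(full$res)) return(bad)
  fit <- full$res$fit
  P <- ncol(X)
  # Wald covariance of beta: Schur complement of the penalized information
  W <- fit$W
  xtwx <- crossprod(X * sqrt(W))
  Vb <- if (length(fit$u)) {
    ztwz <- crossprod(fit$Z * sqrt(W))
    diag(ztwz) <- diag(ztwz) + fit$pen[-seq_len(P)]
    xtwz <- crossprod(X * W, fit$Z)
    tryCatch(solve(xtwx - xtwz %*% solve(ztwz, t(xtwz))), error = function(e) NULL)
  } else tryCatch(solve(xtwx), error = function(e) NULL)
  if (is.null(Vb)) return(bad)
  beta_c <- sum(contrast * fit$beta)
  se <- sqrt(drop(t(contrast) %*% Vb %*% contrast))
  sep <- max(abs(fit$eta)) > 25 || se > 50
  if (test == "wald") {
    stat <- beta_c / se
    p <- if (sep || !fit$converged) NA_real_ else 2 * pnorm(-abs(stat))
  } else {
    rp <- reparam_contrast(X, contrast)
    null_fit <- optimize_model(rp$design[, -ncol(rp$design), drop = FALSE])
    # under complete separation the likelihood still has a finite limit, so
    # the LRT (unlike Wald) remains informative there
    stat <- if (is.null(null_fit$res)) NA_real_
            else max(0, 2 * (full$res$ll - null_fit$res$ll))
    p <- if (is.na(stat) || !is.finite(stat)) NA_real_
         else pchisq(stat, df = 1, lower.tail = FALSE)
  }
  list(beta = beta_c, se = se, stat = stat, p_val = p,
       sigma = setNames(exp(full$logsd), names(Zs)),
       loglik = full$res$ll, ok = fit$converged && !sep)
}

#' Linear (mixed) model fit for one response series
#'
#' REML linear mixed model with the stated random intercepts and per-sample
#' precision weights (proportional to cells per sample). The contrast is
#' tested with a t statistic on Satterthwaite denominator degrees of
#' freedom (falling back to a Wald z when the degrees-of-freedom
#' approximation fails); with no random terms this reduces to ordinary
#' weighted least squares with a t test. A constant response
#' returns effect 0 with p = 1 by convention; non-convergence is flagged
#' with a missing p-value (variance components at the boundary are accepted).
#'
#' @param y per-sample response (NA rows dropped).
#' @param design fixed-effects design matrix.
#' @param random named list of per-sample factors for random intercepts.
#' @param contrast contrast vector.
#' @param weights optional per-sample weights.
#' @return list with `beta`, `se`, `stat`, `p_val`, `df`, `ok`.
#' @export
fit_lmm <- function(y, design, random = list(), contrast, weights = NULL) {
  S <- length(y)
  w <- weights %||% rep(1, S)
  keep <- is.finite(y) & is.finite(w) & w > 0
  bad <- list(beta = NA_real_, se = NA_real_, stat = NA_real_,
              p_val = NA_real_, df = NA_real_, ok = FALSE)
  if (sum(keep) <= ncol(design)) return(bad)
  yk <- y[keep]; Xk <- design[keep, , drop = FALSE]; wk <- w[keep]
  if (var(yk) < 1e-12)
    return(list(beta = 0, se = 0, stat = 0, p_val = 1,
                df = sum(keep) - ncol(design), ok = TRUE))
  if (length(random) == 0L) {
    da <- drop_aliased(Xk, contrast)
    if (!isTRUE(da$ok)) return(bad)
    Xk <- da$X; ctr <- da$contrast
    fit <- lm.wfit(Xk, yk, wk)
    df <- sum(keep) - ncol(Xk)
    if (df < 1L) return(bad)
    s2 <- sum(wk * fit$residuals^2) / df
    xtxinv <- chol2inv(chol(crossprod(Xk * sqrt(wk))))
    beta_c <- sum(ctr * fit$coefficients)
    se <- sqrt(s2 * drop(t(ctr) %*% xtxinv %*% ctr))
    stat <- beta_c / se
    return(list(beta = beta_c, se = se, stat = stat,
                p_val = 2 * pt(-abs(stat), df), df = df, ok = TRUE))
  }
  dat <- as.data.frame(Xk)
  names(dat) <- paste0("b", seq_len(ncol(Xk)))
  dat$.y <- yk
  dat$.w <- wk
  rterms <- character(0)
  for (nm in names(random)) {
    dat[[paste0("r_", nm)]] <- droplevels(factor(random[[nm]])[keep])
    rterms <- c(rterms, paste0("(1 | r_", nm, ")"))
  }
  fml <- stats::as.formula(paste(".y ~ 0 +",
                                 paste(names(dat)[seq_len(ncol(Xk))], collapse = " + "),
                                 "+", paste(rterms, collapse = " + ")))
  fit <- tryCatch(
    suppressMessages(suppressWarnings(
      lmerTest::lmer(fml, data = dat, weights = dat$.w, REML = TRUE,
                     control = lme4::lmerControl(check.conv.singular = "ignore")))),
    error = function(e) NULL)
  if (is.null(fit)) return(bad)
  ct <- tryCatch(
    suppressMessages(suppressWarnings(lmerTest::contest1D(fit, contrast))),
    error = function(e) NULL)
  if (!is.null(ct) && is.finite(ct[["df"]]) && ct[["df"]] > 0) {
    return(list(beta = ct[["Estimate"]], se = ct[["Std. Error"]],
                stat = ct[["t value"]], p_val = ct[["Pr(>|t|)"]],
                df = ct[["df"]], ok = TRUE))
  }
  b <- lme4::fixef(fit)
  V <- as.matrix(vcov(fit))
  beta_c <- sum(contrast * b)
  se <- sqrt(drop(t(contrast) %*% V %*% contrast))
  stat <- beta_c / se
  list(beta = beta_c, se = se, stat = stat, p_val = 2 * pnorm(-abs(stat)),
       df = NA_real_, ok = TRUE)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment across the supplied tests; missing p-values
#' (filtered or non-converged units) are excluded from the adjustment and
#' reinserted as missing.
#'
#' @param p vector of raw p-values (NA allowed).
#' @return vector of BH-adjusted p-values.
#' @export
bh_adjust <- function(p) {
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE))
  out <- rep(NA_real_, length(p))
  ok <- !is.na(p)
  out[ok] <- p.adjust(p[ok], method = "BH")
  out
}
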