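## REML machinery for kinship mixed models
##   y = X b + sum_i g_i + e,   g_i ~ N(0, K_i * sigma2_i),  e ~ N(0, I sigma2_e)
##
## Single-kinship fits use the eigendecomposition profile likelihood (one
## eigendecomposition, then a 1-D search over the variance ratio). Multi-
## kinship fits maximize the REML log-likelihood directly over log-variances
## via L-BFGS-B; at the population sizes this package targets (n of a few
## hundred) each likelihood evaluation is a single Cholesky factorization.

## REML log-likelihood (up to an additive constant) for given variances.
reml_loglik <- function(sigma2, Klist, y, X) {
  n <- length(y)
  p <- ncol(X)
  V <- diag(sigma2[length(sigma2)], n)
  for (i in seq_along(Klist)) V <- V + sigma2[i] * Klist[[i]]
  ch <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(ch)) return(-Inf)
  logdetV <- 2 * sum(log(diag(ch)))
  Vi_y <- backsolve(ch, forwardsolve(t(ch), y))
  Vi_X <- backsolve(ch, forwardsolve(t(ch), X))
  XtViX <- crossprod(X, Vi_X)
  b <- solve(XtViX, crossprod(Vi_X, y))
  Py <- Vi_y - Vi_X %*% b
  -0.5 * (logdetV + determinant(XtViX, logarithm = TRUE)$modulus +
            sum(y * Py))
}

## Single-kinship REML via eigendecomposition: profile over the ratio
## lambda = sigma2_g / sigma2_e with sigma2_e profiled out analytically.
reml_single <- function(y, K, X = matrix(1, length(y), 1)) {
  n <- length(y)
  p <- ncol(X)
  eg <- eigen(K, symmetric = TRUE)
  d <- pmax(eg$values, 0)
  U <- eg$vectors
  ys <- crossprod(U, y)
  Xs <- crossprod(U, X)
  prof <- function(loglam) {
    lam <- exp(loglam)
    w <- 1 / (lam * d + 1)
    XtWX <- crossprod(Xs, Xs * w)
    b <- solve(XtWX, crossprod(Xs, ys * w))
    r <- ys - Xs %*% b
    rss <- sum(w * r^2)
    s2e <- rss / (n - p)
    -0.5 * ((n - p) * log(s2e) + sum(log(lam * d + 1)) +
              determinant(XtWX, logarithm = TRUE)$modulus + (n - p))
  }
  opt <- stats::optimize(prof, interval = c(-25, 25), maximum = TRUE,
                         tol = 1e-9)
  lam <- exp(opt$maximum)
  w <- 1 / (lam * d + 1)
  XtWX <- crossprod(Xs, Xs * w)
  b <- solve(XtWX, crossprod(Xs, ys * w))
  r <- ys - Xs %*% b
  s2e <- sum(w * r^2) / (n - p)
  s2g <- lam * s2e
  # BLUP of g: sigma2_g K V^-1 (y - Xb) in the eigenbasis
  g <- U %*% (lam * d * w * r)
  list(sigma2 = c(s2g, s2e), beta = drop(b), g = drop(g),
       loglik = opt$objective, lambda = lam)
}

## Multi-kinship REML (direct maximization over log variances).
reml_multi <- function(y, Klist, X = matrix(1, length(y), 1),
                       maxit = 200) {
  n <- length(y)
  vy <- stats::var(y)
  k <- length(Klist)
  init <- log(rep(vy / (k + 1), k + 1))
  nll <- function(theta) -reml_loglik(exp(theta), Klist, y, X)
  opt <- stats::optim(init, nll, method = "L-BFGS-B",
                      lower = log(vy) - 25, upper = log(vy) + 10,
                      control = list(maxit = maxit))
  if (opt$convergence != 0) {
    opt2 <- stats::optim(opt$par, nll, method = "Nelder-Mead",
                         control = list(maxit = 2000))
    if (opt2$value <= opt$value) opt <- opt2
  }
  sigma2 <- exp(opt$par)
  V <- diag(sigma2[k + 1], n)
  for (i in seq_len(k)) V <- V + sigma2[i] * Klist[[i]]
  ch <- chol(V)
  Vi_y <- backsolve(ch, forwardsolve(t(ch), y))
  Vi_X <- backsolve(ch, forwardsolve(t(ch), X))
  b <- solve(crossprod(X, Vi_X), crossprod(Vi_X, y))
  Py <- Vi_y - Vi_X %*% b
  g <- lapply(seq_len(k), function(i) drop(sigma2[i] * Klist[[i]] %*% Py))
  list(sigma2 = sigma2, beta = drop(b), g = g,
       loglik = -opt$value, Py = drop(Py))
}

## Gibbs sampler for kinship mixed models, in the eigenbasis of each kinship
## (orthonormal loadings make every full conditional diagonal). Scaled
## inverse-chi-square priors, df 5, scales set from var(y) with an even split
## of an R2 = 0.5 prior guess across genetic terms.
gibbs_kinship <- function(y, Klist, niter = 6000, burnin = 1000, thin = 5,
                          seed = 1L, df_prior = 5, R2 = 0.5) {
  n <- length(y)
  k <- length(Klist)
  eg <- lapply(Klist, function(K) {
    e <- eigen(K, symmetric = TRUE)
    keep <- e$values > 1e-8
    list(U = e$vectors[, keep, drop = FALSE], d = e$values[keep])
  })
  vy <- stats::var(y)
  S_g <- (R2 * vy / k) * (df_prior - 2) / df_prior
  S_e <- ((1 - R2) * vy) * (df_prior - 2) / df_prior
  with_seed(seed, {
    mu <- mean(y)
    s2 <- rep(R2 * vy / k, k)
    s2e <- (1 - R2) * vy
    alpha <- lapply(eg, function(z) numeric(length(z$d)))
    gsum <- lapply(eg, function(z) numeric(n))
    e <- y - mu
    musum <- 0; s2sum <- numeric(k); s2esum <- 0; nsave <- 0
    draws <- matrix(NA_real_, 0, k + 1)
    for (it in seq_len(niter)) {
      # genetic blocks
      for (i in seq_len(k)) {
        Ui <- eg[[i]]$U; di <- eg[[i]]$d
        e <- e + drop(Ui %*% alpha[[i]])
        rhs <- drop(crossprod(Ui, e)) / s2e
        prec <- 1 / s2e + 1 / (di * s2[i])
        alpha[[i]] <- stats::rnorm(length(di), rhs / prec, sqrt(1 / prec))
        e <- e - drop(Ui %*% alpha[[i]])
        ss <- sum(alpha[[i]]^2 / di)
        s2[i] <- (ss + df_prior * S_g) /
          stats::rchisq(1, length(di) + df_prior)
      }
      # intercept
      e <- e + mu
      mu <- stats::rnorm(1, mean(e), sqrt(s2e / n))
      e <- e - mu
      # residual variance
      s2e <- (sum(e^2) + df_prior * S_e) / stats::rchisq(1, n + df_prior)
      if (it > burnin && (it - burnin) %% thin == 0) {
        nsave <- nsave + 1
        musum <- musum + mu
        s2sum <- s2sum + s2
        s2esum <- s2esum + s2e
        for (i in seq_len(k)) gsum[[i]] <- gsum[[i]] + drop(eg[[i]]$U %*% alpha[[i]])
        draws <- rbind(draws, c(s2, s2e))
      }
    }
    list(sigma2 = c(s2sum / nsave, s2esum / nsave), beta = musum / nsave,
         g = lapply(gsum, function(z) z / nsave), draws = draws)
  })
}
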