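#' @useDynLib hybridgs, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

new_gs_fit <- function(family, effects, mu, vc, fitted, ids, y, extra = list()) {
  structure(c(list(
    family = family, effects = effects, mu = mu, vc = vc,
    fitted = setNames(fitted, ids), train_ids = ids, y = setNames(y, ids)
  ), extra), class = "gs_fit")
}

#' @export
print.gs_fit <- function(x, ...) {
  cat(sprintf("gs_fit: %s (%s effects), n = %d\n", x$family, x$effects,
              length(x$train_ids)))
  if (!is.null(x$vc)) {
    cat("  variance components:",
        paste(sprintf("%s = %.4g", names(x$vc), unlist(x$vc)), collapse = ", "),
        "\n")
  }
  invisible(x)
}

align_kinship <- function(K, ids) {
  miss <- setdiff(ids, rownames(K))
  if (length(miss)) stop("IDs absent from kinship: ", paste(miss, collapse = ", "))
  K[ids, ids, drop = FALSE]
}

check_psd <- function(K, tol = 1e-6) {
  if (max(abs(K - t(K))) > 1e-8) stop("kinship matrix is not symmetric")
  ev <- min(eigen(K, symmetric = TRUE, only.values = TRUE)$values)
  if (ev < -tol * max(1, max(abs(diag(K))))) {
    stop("kinship matrix is not positive semi-definite (min eigenvalue ", ev, ")")
  }
  invisible(K)
}

#' Fit a GBLUP model
#'
#' Mixed model `y = 1 mu + g_A (+ g_D) + e` with
#' `g_A ~ N(0, A sigma2_A)`, optionally `g_D ~ N(0, D sigma2_D)`.
#' The REML engine (default) uses an eigendecomposition profile likelihood
#' for the additive-only model and direct REML maximization for the joint
#' additive + dominance model; the Gibbs engine samples the same model with
#' scaled-inverse-chi-square variance priors and returns posterior means
#' (plus variance-component draws for posterior-summary heritability).
#'
#' @param y named numeric vector of phenotypes (names = individual IDs)
#' @param A additive kinship matrix (from [additive_kinship()])
#' @param D optional dominance kinship matrix; supplying it fits the
#'   additive-plus-dominance model
#' @param engine `"REML"` or `"Gibbs"`
#' @param niter,burnin,thin,seed Gibbs chain controls (ignored under REML)
#' @return a `gs_fit` with variance components, intercept, per-individual
#'   genetic-value BLUPs and fitted values
#' @export
fit_gblup <- function(y, A, D = NULL, engine = c("REML", "Gibbs"),
                      niter = 12000, burnin = 2000, thin = 5, seed = 1L) {
  engine <- match.arg(engine)
  stopifnot(!is.null(names(y)))
  ids <- names(y)
  A <- check_psd(align_kinship(A, ids))
  Klist <- list(A = A)
  if (!is.null(D)) Klist$D <- check_psd(align_kinship(D, ids))
  effects <- if (is.null(D)) "additive" else "additive_dominant"
  if (engine == "REML") {
    fit <- if (is.null(D)) reml_single(y, A) else reml_multi(y, Klist)
    gA <- if (is.null(D)) fit$g else fit$g[[1]]
    gD <- if (is.null(D)) NULL else fit$g[[2]]
    vc <- list(sigma2_A = fit$sigma2[1],
               sigma2_D = if (is.null(D)) NULL else fit$sigma2[2],
               sigma2_e = fit$sigma2[length(fit$sigma2)])
    mu <- fit$beta[1]
    draws <- NULL
    loglik <- fit$loglik
  } else {
    fit <- gibbs_kinship(y, Klist, niter = niter, burnin = burnin,
                         thin = thin, seed = seed)
    gA <- fit$g[[1]]
    gD <- if (is.null(D)) NULL else fit$g[[2]]
    vc <- list(sigma2_A = fit$sigma2[1],
               sigma2_D = if (is.null(D)) NULL else fit$sigma2[2],
               sigma2_e = fit$sigma2[length(fit$sigma2)])
    mu <- fit$beta
    draws <- fit$draws
    loglik <- NA_real_
  }
  vc <- vc[!vapply(vc, is.null, logical(1))]
  fitted <- mu + gA + if (is.null(gD)) 0 else gD
  new_gs_fit("GBLUP", effects, mu, vc, fitted, ids, y,
             extra = list(gA = setNames(gA, ids),
                          gD = if (is.null(gD)) NULL else setNames(gD, ids),
                          engine = engine, vc_draws = draws, loglik = loglik,
                          seed = seed))
}

#' Predict genetic values of new individuals from a GBLUP fit
#'
#' Standard mixed-model conditional mean: with `V = sigma2_A A_tt (+
#' sigma2_D D_tt) + sigma2_e I` over the training block and `C` the
#' genetic-covariance block between test and training individuals,
#' predictions are `mu + C V^-1 (y - mu)`.
#'
#' @param fit a `gs_fit` from [fit_gblup()] (or [fit_rkhs()])
#' @param A_full kinship covering training and test individuals (same flavor
#'   as the fit's A; for RKHS fits the Gaussian kernel over both sets)
#' @param D_full optional dominance kinship over both sets (AD fits only)
#' @param test_ids IDs to predict (default: all rows of `A_full`)
#' @return named numeric vector of predictions
#' @export
predict_gblup <- function(fit, A_full, D_full = NULL, test_ids = NULL) {
  if (is.null(test_ids)) test_ids <- rownames(A_full)
  tr <- fit$train_ids
  miss <- setdiff(c(tr, test_ids), rownames(A_full))
  if (length(miss)) stop("IDs absent from kinship: ", paste(miss, collapse = ", "))
  s2A <- fit$vc$sigma2_A
  s2e <- fit$vc$sigma2_e
  Vtt <- s2A * A_full[tr, tr, drop = FALSE] + diag(s2e, length(tr))
  Cts <- s2A * A_full[test_ids, tr, drop = FALSE]
  if (!is.null(fit$vc$sigma2_D)) {
    if (is.null(D_full)) stop("fit includes dominance: supply D_full")
    s2D <- fit$vc$sigma2_D
    Vtt <- Vtt + s2D * D_full[tr, tr, drop = FALSE]
    Cts <- Cts + s2D * D_full[test_ids, tr, drop = FALSE]
  }
  # small ridge only inside the solve, never on stored matrices
  Vtt <- Vtt + diag(1e-8 * mean(diag(Vtt)), nrow(Vtt))
  ghat <- drop(Cts %*% solve(Vtt, fit$y[tr] - fit$mu))
  setNames(fit$mu + ghat, test_ids)
}

## data-scaled hyperparameters shared by the marker-effect samplers
marker_prior_scales <- function(y, X, pi_zero, df_beta = 5, df_e = 5,
                                R2 = 0.5) {
  vy <- stats::var(y)
  if (vy <= 0) vy <- 1e-8
  sumvar <- sum(apply(X, 2, stats::var))
  if (sumvar <= 0) sumvar <- 1e-8
  Ebeta2 <- R2 * vy / ((1 - pi_zero) * sumvar)
  list(S_beta = Ebeta2 * (df_beta - 2) / df_beta,
       S_e = (1 - R2) * vy * (df_e - 2) / df_e,
       sumvar = sumvar, vy = vy)
}

#' Fit a Bayes B marker-effect model
#'
#' Gibbs sampler for `y = 1 mu + X_add beta + X_het delta + e` with
#' spike-and-slab priors on every marker effect: zero with probability
#' `pi_zero`, otherwise normal with a per-marker variance carrying a scaled
#' inverse-chi-square prior (df `df_beta`, data-scaled scale), which
#' marginally gives the scaled-t slab.  The heterozygosity design (if any) is
#' column-centered and concatenated with the genotype design.
#'
#' @param y named phenotype vector
#' @param X_add individuals x markers coded \{-1,0,1\} genotype matrix
#' @param X_het optional heterozygosity design ([heterozygosity_design()]);
#'   supplying it fits the additive-plus-dominance variant
#' @param niter,burnin,thin chain controls
#' @param pi_zero prior probability a marker effect is exactly zero
#' @param sample_pi update `pi_zero` under a flat Beta hyperprior
#' @param df_beta,df_e prior degrees of freedom
#' @param seed integer seed (chains are bit-reproducible)
#' @return a `gs_fit` with posterior-mean intercept and marker effects
#' @export
fit_markers_bayesB <- function(y, X_add, X_het = NULL, niter = 12000,
                               burnin = 2000, thin = 5, pi_zero = 0.95,
                               sample_pi = FALSE, df_beta = 5, df_e = 5,
                               seed = 1L) {
  fit_markers(y, X_add, X_het, "BayesB", niter, burnin, thin, pi_zero,
              sample_pi, df_beta, df_e, seed)
}

#' Fit a Bayesian Lasso marker-effect model
#'
#' Gibbs sampler with double-exponential (Laplace) priors on marker effects
#' via the exponential scale-mixture-of-normals representation; the
#' regularization parameter `lambda^2` carries a gamma hyperprior and is
#' sampled.
#'
#' @inheritParams fit_markers_bayesB
#' @return a `gs_fit` with posterior-mean intercept and marker effects
#' @export
fit_markers_blasso <- function(y, X_add, X_het = NULL, niter = 12000,
                               burnin = 2000, thin = 5, df_e = 5, seed = 1L) {
  fit_markers(y, X_add, X_het, "BayesianLasso", niter, burnin, thin,
              pi_zero = 0, sample_pi = FALSE, df_beta = 5, df_e = df_e, seed)
}

fit_markers <- function(y, X_add, X_het, family, niter, burnin, thin,
                        pi_zero, sample_pi, df_beta, df_e, seed) {
  stopifnot(!is.null(names(y)), niter > burnin)
  ids <- names(y)
  X_add <- as.matrix(X_add)[ids, , drop = FALSE]
  if (!all(is.finite(X_add))) stop("non-finite values in genotype design")
  m_add <- ncol(X_add)
  het_center <- NULL
  if (!is.null(X_het)) {
    X_het <- as.matrix(X_het)[ids, , drop = FALSE]
    het_center <- colMeans(X_het)
    X_het <- sweep(X_het, 2, het_center)  # centered for identifiability
    X <- cbind(X_add, X_het)
  } else {
    X <- X_add
  }
  effects <- if (is.null(X_het)) "additive" else "additive_dominant"
  if (family == "BayesB") {
    sc <- marker_prior_scales(y, X, pi_zero, df_beta, df_e)
    out <- with_seed(seed, .bayesb_sampler(
      as.numeric(y), X, as.integer(niter), as.integer(burnin),
      as.integer(thin), pi_zero, df_beta, sc$S_beta, df_e, sc$S_e, sample_pi))
  } else {
    sc <- marker_prior_scales(y, X, 0, df_beta, df_e)
    lambda2_0 <- 2 * sc$S_e * ncol(X) / max(sc$vy * 0.5, 1e-8)
    out <- with_seed(seed, .blasso_sampler(
      as.numeric(y), X, as.integer(niter), as.integer(burnin),
      as.integer(thin), lambda2_0, 1.1, 1.1 / lambda2_0, df_e, sc$S_e))
  }
  beta <- out$beta
  beta_add <- setNames(beta[seq_len(m_add)], colnames(X_add))
  beta_het <- if (is.null(X_het)) NULL else {
    setNames(beta[m_add + seq_len(ncol(X_het))], colnames(X_add))
  }
  fitted <- drop(out$mu + X %*% beta)
  new_gs_fit(family, effects, out$mu,
             list(sigma2_e = out$sigma2e), fitted, ids, y,
             extra = list(beta_add = beta_add, beta_het = beta_het,
                          incl_prob = out$incl_prob, seed = seed,
                          niter = niter, burnin = burnin,
                          het_center = het_center))
}

#' Predict from a marker-effect fit
#'
#' `mu + X_add beta_add (+ X_het_centered delta)`; the heterozygosity design
#' of new individuals is centered by the training-column means implicitly via
#' re-centering against the training fit (the intercept absorbs the offset).
#'
#' @param fit a `gs_fit` from [fit_markers_bayesB()] or [fit_markers_blasso()]
#' @param X_add coded genotype matrix of individuals to predict
#' @param X_het optional heterozygosity design of the same individuals
#'   (uncentered \{0,1\} indicators are fine)
#' @return named numeric vector of predictions
#' @export
predict_markers <- function(fit, X_add, X_het = NULL) {
  X_add <- as.matrix(X_add)
  pred <- drop(fit$mu + X_add %*% fit$beta_add)
  if (!is.null(fit$beta_het)) {
    if (is.null(X_het)) stop("fit includes dominance effects: supply X_het")
    X_het <- as.matrix(X_het)
    ctr <- fit$het_center
    if (!is.null(ctr)) X_het <- sweep(X_het, 2, ctr)
    pred <- pred + drop(X_het %*% fit$beta_het)
  }
  setNames(pred, rownames(X_add))
}

#' Gaussian kernel from coded genotypes
#'
#' `K_ij = exp(-theta * d2_ij / median(d2))` where `d2` is the squared
#' Euclidean distance between coded genotype rows and the median is taken
#' over off-diagonal training distances (the classical median heuristic).
#'
#' @param M coded genotype matrix (rows = individuals)
#' @param theta bandwidth multiplier (default 1)
#' @param M2 optional second matrix: returns the cross-kernel rows(M) x rows(M2)
#' @param d2_scale optional precomputed median squared distance (reuse the
#'   training median when computing test-vs-train cross-kernels)
#' @return kernel matrix; attribute `d2_scale` carries the median used
#' @export
gaussian_kernel <- function(M, theta = 1, M2 = NULL, d2_scale = NULL) {
  M <- as.matrix(M)
  self <- is.null(M2)
  if (self) M2 <- M
  d2 <- outer(rowSums(M^2), rowSums(M2^2), "+") - 2 * tcrossprod(M, M2)
  d2[d2 < 0] <- 0
  if (is.null(d2_scale)) {
    off <- if (self) d2[lower.tri(d2)] else d2
    d2_scale <- stats::median(off)
    if (!is.finite(d2_scale) || d2_scale <= 0) {
      stop("degenerate genotypes: zero median squared distance")
    }
  }
  K <- exp(-theta * d2 / d2_scale)
  dimnames(K) <- list(rownames(M), rownames(M2))
  attr(K, "d2_scale") <- d2_scale
  K
}

#' Fit an RKHS regression model
#'
#' Builds a Gaussian kernel over the coded genotypes and treats it as the
#' genetic covariance in a single-kinship mixed model (REML path shared with
#' [fit_gblup()]).  Dominance-style nonlinearity is captured by the kernel
#' itself, so no separate dominance term is accepted.
#'
#' @param y named phenotype vector
#' @param G a fully imputed [genotype_matrix()] (or a coded matrix)
#' @param theta kernel bandwidth multiplier; `"AUTO"` means 1 (median
#'   heuristic scaling)
#' @return a `gs_fit`; prediction uses [predict_rkhs()]
#' @export
fit_rkhs <- function(y, G, theta = "AUTO") {
  if (identical(theta, "AUTO")) theta <- 1
  M <- if (inherits(G, "GenotypeMatrix")) G$calls else as.matrix(G)
  ids <- names(y)
  M_train <- M[ids, , drop = FALSE]
  K <- gaussian_kernel(M_train, theta)
  fit <- reml_single(y, K)
  vc <- list(sigma2_A = fit$sigma2[1], sigma2_e = fit$sigma2[2])
  fitted <- fit$beta[1] + fit$g
  new_gs_fit("RKHS", "additive", fit$beta[1], vc, fitted, ids, y,
             extra = list(gA = setNames(fit$g, ids), engine = "REML",
                          theta = theta, M_train = M_train,
                          d2_scale = attr(K, "d2_scale"), loglik = fit$loglik))
}

#' Predict from an RKHS fit
#' @param fit a `gs_fit` from [fit_rkhs()]
#' @param M_test coded genotype matrix (or [genotype_matrix()]) of individuals
#'   to predict
#' @return named numeric vector of predictions
#' @export
predict_rkhs <- function(fit, M_test) {
  if (inherits(M_test, "GenotypeMatrix")) M_test <- M_test$calls
  Cts <- gaussian_kernel(M_test, fit$theta, M2 = fit$M_train,
                         d2_scale = fit$d2_scale)
  Ktt <- gaussian_kernel(fit$M_train, fit$theta, d2_scale = fit$d2_scale)
  s2g <- fit$vc$sigma2_A
  s2e <- fit$vc$sigma2_e
  Vtt <- s2g * Ktt + diag(s2e + 1e-8 * s2g, nrow(Ktt))
  ghat <- drop(s2g * Cts %*% solve(Vtt, fit$y - fit$mu))
  setNames(fit$mu + ghat, rownames(M_test))
}

#' Fit a random forest on coded genotypes
#'
#' Delegates to \pkg{randomForest}; trees split on the raw \{-1,0,1\} codes,
#' so heterozygote-specific (dominance-like) effects are representable
#' without an explicit dominance design.
#'
#' @param y named phenotype vector
#' @param X_add coded genotype matrix
#' @param ntree number of trees
#' @param seed integer seed
#' @param ... passed to [randomForest::randomForest()]
#' @return a `gs_fit`; predict with [predict_forest()]
#' @export
fit_tree_ensemble <- function(y, X_add, ntree = 500, seed = 1L, ...) {
  ids <- names(y)
  X <- as.matrix(X_add)[ids, , drop = FALSE]
  rf <- with_seed(seed, randomForest::randomForest(x = X, y = as.numeric(y),
                                                   ntree = ntree, ...))
  fitted <- with_seed(seed, stats::predict(rf, X))
  new_gs_fit("TreeEnsemble", "additive", mean(y), NULL, fitted, ids, y,
             extra = list(forest = rf, seed = seed))
}

#' Predict from a random-forest fit
#' @param fit a `gs_fit` from [fit_tree_ensemble()]
#' @param X_add coded genotype matrix of individuals to predict
#' @return named numeric vector of predictions
#' @export
predict_forest <- function(fit, X_add) {
  p <- stats::predict(fit$forest, as.matrix(X_add))
  setNames(as.numeric(p), rownames(X_add))
}
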