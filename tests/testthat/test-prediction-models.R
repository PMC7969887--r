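# population fixtures shared across the model tests
f1_population <- function(n_parents, n_crosses, n_markers, seed) {
  P <- small_panel(n_lines = n_parents, n_markers = n_markers, seed = seed)
  synthesize_hybrids(P, sample_plan(individuals(P), n_crosses,
                                    seed = seed + 1))
}

test_that("GBLUP reproduces a noiseless genetic signal", {
  G <- f1_population(20, 60, 400, seed = 101)
  A <- additive_kinship(G)
  eg <- eigen(A, symmetric = TRUE)
  set.seed(5)
  g <- drop(eg$vectors %*% (sqrt(pmax(eg$values, 0)) * rnorm(nrow(A))))
  y <- setNames(g, rownames(A))
  fit <- fit_gblup(y, A)
  expect_lt(max(abs(fit$fitted - y)), 1e-6)
  expect_lt(fit$vc$sigma2_e, 1e-6)
})

test_that("single-kinship REML matches a grid-search profile-likelihood oracle", {
  G <- f1_population(20, 50, 400, seed = 103)
  A <- additive_kinship(G)
  tr <- assign_trait_architecture(G, 100, sigma2_A = 1, seed = 7)
  y <- simulate_phenotypes(tr, G, sigma2_e = 0.8, seed = 8)
  fit <- fit_gblup(y, A)
  oracle <- grid_reml_oracle(y, A)
  # agreement to 3 significant figures
  expect_equal(fit$vc$sigma2_A, oracle[["sigma2_A"]], tolerance = 1e-3)
  expect_equal(fit$vc$sigma2_e, oracle[["sigma2_e"]], tolerance = 1e-3)
})

test_that("additive GBLUP is dual to ridge marker regression", {
  set.seed(21)
  n <- 30; m <- 500
  X <- matrix(sample(c(-1, 0, 1), n * m, TRUE), n, m)
  X <- scale(X, scale = FALSE)
  rownames(X) <- paste0("i", seq_len(n))
  cc <- sum(colMeans(X^2))
  A <- tcrossprod(X) / cc
  dimnames(A) <- list(rownames(X), rownames(X))
  y <- setNames(drop(X %*% rnorm(m, 0, 0.05)) + rnorm(n), rownames(X))
  fit <- fit_gblup(y, A)
  lambda <- fit$vc$sigma2_e / (fit$vc$sigma2_A / cc)
  beta <- solve(crossprod(X) + diag(lambda, m), crossprod(X, y - fit$mu))
  ridge_fitted <- fit$mu + drop(X %*% beta)
  expect_lt(max(abs(ridge_fitted - fit$fitted)), 1e-6)
})

test_that("GBLUP recovers a known heritability on average", {
  h2 <- replicate(20, {
    seed <- sample.int(1e6, 1)
    P <- simulate_inbred_panel(n_lines = 50, n_markers = 800, seed = seed)$lines
    G <- synthesize_hybrids(P, sample_plan(individuals(P), 200, seed = seed + 1))
    tr <- assign_trait_architecture(G, 250, sigma2_A = 0.6, seed = seed + 2)
    y <- simulate_phenotypes(tr, G, sigma2_e = 0.4, seed = seed + 3)
    h2_additive(fit_gblup(y, additive_kinship(G))$vc)
  })
  expect_lt(abs(mean(h2) - 0.6), 0.1)
})

test_that("GBLUP prediction is the mixed-model conditional mean", {
  G <- f1_population(20, 60, 400, seed = 105)
  A <- additive_kinship(G)
  tr <- assign_trait_architecture(G, 100, sigma2_A = 1, seed = 9)
  y <- simulate_phenotypes(tr, G, sigma2_e = 0.5, seed = 10)
  fit <- fit_gblup(y, A)
  # test set = train set -> predictions equal fitted values
  pred <- predict_gblup(fit, A, test_ids = names(y))
  expect_equal(unname(pred), unname(fit$fitted), tolerance = 1e-6)
  # an individual unrelated to all training lines is predicted at mu
  A2 <- rbind(cbind(A, unrel = 0), unrel = 0)
  A2["unrel", "unrel"] <- 1
  expect_equal(unname(predict_gblup(fit, A2, test_ids = "unrel")), fit$mu,
               tolerance = 1e-8)
})

test_that("dominance term never decreases in-sample fit", {
  for (seed in c(301, 302, 303)) {
    G <- f1_population(15, 60, 300, seed = seed)
    tr <- assign_trait_architecture(G, 100, sigma2_A = 1, sigma2_D = 0.5,
                                    seed = seed)
    y <- simulate_phenotypes(tr, G, sigma2_e = 1, seed = seed + 1)
    A <- additive_kinship(G)
    D <- dominance_kinship(G)
    r2A <- cor(fit_gblup(y, A)$fitted, y)^2
    r2AD <- cor(fit_gblup(y, A, D)$fitted, y)^2
    expect_gte(r2AD, r2A - 1e-6)
  }
})

test_that("Gibbs engine agrees with REML and yields reproducible chains", {
  G <- f1_population(20, 80, 400, seed = 107)
  A <- additive_kinship(G)
  tr <- assign_trait_architecture(G, 150, sigma2_A = 1.5, seed = 11)
  y <- simulate_phenotypes(tr, G, sigma2_e = 1, seed = 12)
  fr <- fit_gblup(y, A)
  fg <- fit_gblup(y, A, engine = "Gibbs", niter = 3000, burnin = 500, seed = 3)
  expect_lt(abs(h2_additive(fg$vc) - h2_additive(fr$vc)), 0.15)
  fg2 <- fit_gblup(y, A, engine = "Gibbs", niter = 3000, burnin = 500, seed = 3)
  expect_identical(fg$vc, fg2$vc)
  expect_true(all(dim(fg$vc_draws) == c(500, 2)))
})

test_that("Bayes B shrinks noise but keeps planted signal, and chains are reproducible", {
  G <- f1_population(25, 120, 200, seed = 109)
  X <- G$calls
  qtl <- as.integer(which.max(apply(X, 2, var)))
  set.seed(31)
  contrast <- replicate(10, {
    y_noise <- setNames(rnorm(nrow(X)), rownames(X))
    f_noise <- fit_markers_bayesB(y_noise, X, niter = 2000, burnin = 500,
                                  seed = sample.int(1e6, 1))
    # planted single QTL worth one phenotypic SD
    y_qtl <- setNames(X[, qtl] * 1 + rnorm(nrow(X), 0, 0.3), rownames(X))
    f_qtl <- fit_markers_bayesB(y_qtl, X, niter = 2000, burnin = 500,
                                seed = sample.int(1e6, 1))
    c(noise = max(abs(f_noise$beta_add)), signal = max(abs(f_qtl$beta_add)),
      hit = as.integer(which.max(abs(f_qtl$beta_add))) == qtl)
  })
  expect_lt(mean(contrast["noise", ]), 0.1 * mean(contrast["signal", ]))
  expect_gte(sum(contrast["hit", ]), 9)
  # bit-for-bit determinism
  y_qtl <- setNames(X[, qtl] + rnorm(nrow(X), 0, 0.3), rownames(X))
  f1 <- fit_markers_bayesB(y_qtl, X, niter = 2000, burnin = 500, seed = 1)
  f2 <- fit_markers_bayesB(y_qtl, X, niter = 2000, burnin = 500, seed = 1)
  expect_identical(f1$beta_add, f2$beta_add)
  expect_identical(f1$mu, f2$mu)
})

test_that("Bayes B ranks a sparse planted architecture in the top tail", {
  # low-LD outbred population (so causal columns are not shadowed by linked
  # proxies) and equal-magnitude planted effects at h2 = 0.8
  set.seed(53)
  hits <- replicate(10, {
    seed <- sample.int(1e6, 1)
    G <- as_genotype_matrix(simulate_founders(300, 400, seed = seed))
    qtl <- sample.int(400, 5)
    beta <- sample(c(-1, 1), 5, TRUE)
    g <- drop(G$calls[, qtl] %*% beta)
    g <- g * sqrt(4 / var(g))            # sigma2_A = 4, sigma2_e = 1
    y <- setNames(g + rnorm(300), individuals(G))
    fit <- fit_markers_bayesB(y, G$calls, niter = 3000, burnin = 1000,
                              seed = seed + 1)
    ranks <- rank(-abs(fit$beta_add))[qtl]
    all(ranks <= 0.05 * ncol(G$calls))
  })
  expect_gte(sum(hits), 8)
})

test_that("Bayesian Lasso handles degenerate input and matches GBLUP on dense traits", {
  G <- f1_population(25, 150, 350, seed = 111)
  X <- G$calls
  # all-zero phenotype -> intercept and effects at zero
  y0 <- setNames(rep(0, nrow(X)), rownames(X))
  f0 <- fit_markers_blasso(y0, X, niter = 1500, burnin = 500, seed = 2)
  # Monte-Carlo noise floor set by the (tiny) residual-variance prior
  expect_lt(abs(f0$mu), 1e-3)
  expect_lt(max(abs(f0$beta_add)), 1e-3)
  # dense polygenic trait: BL ~ GBLUP equivalence regime
  tr <- assign_trait_architecture(G, 300, sigma2_A = 2, seed = 13)
  y <- simulate_phenotypes(tr, G, sigma2_e = 1, seed = 14)
  fg <- fit_gblup(y, additive_kinship(G))
  fl <- fit_markers_blasso(y, X, niter = 3000, burnin = 1000, seed = 3)
  expect_gt(cor(fl$fitted, fg$fitted), 0.95)
  # doubling the chain moves posterior-mean fitted values only within MC noise
  fl2 <- fit_markers_blasso(y, X, niter = 6000, burnin = 1000, seed = 4)
  expect_gt(cor(fl$fitted, fl2$fitted), 0.999)
})

test_that("RKHS kernel properties and limits hold", {
  G <- f1_population(20, 80, 300, seed = 113)
  K <- gaussian_kernel(G$calls)
  expect_equal(unname(diag(K)), rep(1, nrow(K)))
  tr <- assign_trait_architecture(G, 100, sigma2_A = 1, seed = 15)
  y <- simulate_phenotypes(tr, G, sigma2_e = 0.5, seed = 16)
  fit <- fit_rkhs(y, G)
  # huge bandwidth: kernel -> identity, unrelated test individuals -> mu
  fit_big <- fit_rkhs(y, G, theta = 1e6)
  far <- matrix(-1L, 1, ncol(G$calls))  # distinct from every training line
  far[1, seq(1, ncol(far), 2)] <- 1L
  rownames(far) <- "far"
  expect_equal(unname(predict_rkhs(fit_big, far)), fit_big$mu, tolerance = 1e-4)
  expect_error(fit_rkhs(y, genotype_matrix(matrix(1L, length(y), 3,
    dimnames = list(names(y), NULL)))), "degenerate")
})

test_that("RKHS tolerates dominance variance about as well as additive GBLUP", {
  gap <- replicate(8, {
    seed <- sample.int(1e6, 1)
    P <- simulate_inbred_panel(n_lines = 30, n_markers = 500, seed = seed)$lines
    G <- synthesize_hybrids(P, sample_plan(individuals(P), 160, seed = seed + 1))
    tr <- assign_trait_architecture(G, 150, sigma2_A = 1, sigma2_D = 0.8,
                                    seed = seed + 2)
    y <- simulate_phenotypes(tr, G, sigma2_e = 0.7, seed = seed + 3)
    train <- names(y)[1:110]
    test <- setdiff(names(y), train)
    fk <- fit_rkhs(y[train], G[train, ])
    pk <- predict_rkhs(fk, G[test, ])
    A <- additive_kinship(G, freq = marker_allele_freq(G[train, ]))
    fa <- fit_gblup(y[train], A[train, train])
    pa <- predict_gblup(fa, A, test_ids = test)
    pearson_accuracy(pk, y[test]) - pearson_accuracy(pa, y[test])
  })
  expect_gte(mean(gap), -0.05)
})

test_that("random forest is deterministic and captures a pure-dominance locus", {
  G <- f1_population(20, 100, 200, seed = 115)
  X <- G$calls
  # constant phenotype -> constant predictions
  yc <- setNames(rep(2.5, nrow(X)), rownames(X))
  fc <- suppressWarnings(fit_tree_ensemble(yc, X, ntree = 50, seed = 1))
  expect_true(all(abs(predict_forest(fc, X) - 2.5) < 1e-8))
  # reproducibility under a fixed seed
  set.seed(41)
  y <- setNames(rnorm(nrow(X)), rownames(X))
  f1 <- fit_tree_ensemble(y, X, ntree = 50, seed = 9)
  f2 <- fit_tree_ensemble(y, X, ntree = 50, seed = 9)
  expect_identical(predict_forest(f1, X), predict_forest(f2, X))
  # phenotype depending on heterozygosity only: forest beats the additive model
  het_freq <- colMeans(X == 0L)
  locus <- which.min(abs(het_freq - 0.5))
  set.seed(43)
  yd <- setNames(2 * (X[, locus] == 0L) + rnorm(nrow(X), 0, 0.3), rownames(X))
  train <- rownames(X)[1:70]
  test <- setdiff(rownames(X), train)
  frf <- fit_tree_ensemble(yd[train], X[train, ], ntree = 300, seed = 3)
  acc_rf <- pearson_accuracy(predict_forest(frf, X[test, ]), yd[test])
  A <- additive_kinship(G)
  fa <- fit_gblup(yd[train], A[train, train])
  acc_add <- cor(predict_gblup(fa, A, test_ids = test), yd[test])
  expect_gt(acc_rf, acc_add)
})

test_that("model specs reject dominance variants for RKHS and RF", {
  expect_error(gs_model("RKHS-AD"), "no explicit dominance")
  expect_error(gs_model("RF-AD"), "no explicit dominance")
  expect_error(gs_model("GBLUP"), "unknown model")
  spec <- gs_model("BB-AD", niter = 100)
  expect_equal(spec$family, "BayesB")
  expect_equal(spec$effects, "additive_dominant")
})
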