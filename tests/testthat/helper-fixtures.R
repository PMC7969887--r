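# Shared fixtures, built in code at test time.

# small coded genotype matrix with known content
toy_genotypes <- function() {
  calls <- rbind(
    s1 = c(-1L, 0L, 1L, 1L, NA),
    s2 = c(-1L, 1L, 0L, 1L, 0L),
    s3 = c(1L, 1L, -1L, 1L, 0L)
  )
  colnames(calls) <- paste0("m", 1:5)
  genotype_matrix(calls, data.frame(
    id = paste0("m", 1:5), chrom = c("chr1", "chr1", "chr1", "chr2", "chr2"),
    pos = c(100L, 500L, 2000L, 100L, 900L), stringsAsFactors = FALSE
  ))
}

# 3-sample, 5-site VCF with one triallelic site and one missing GT
write_toy_vcf <- function(path) {
  lines <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "s1", "s2", "s3", sep = "\t"),
    paste("chr1", "100", "v1", "A", "G", ".", "PASS", ".", "GT",
          "0/0", "0/1", "1/1", sep = "\t"),
    paste("chr1", "200", "v2", "C", "T", ".", "PASS", ".", "GT",
          "./.", "0/0", "0/0", sep = "\t"),
    paste("chr1", "300", "v3", "G", "A,T", ".", "PASS", ".", "GT",
          "0/1", "1/2", "0/0", sep = "\t"),
    paste("chr2", "100", "v4", "T", "C", ".", "PASS", ".", "GT",
          "1/1", "0/1", "0/0", sep = "\t"),
    paste("chr2", "250", "v5", "A", "C", ".", "PASS", ".", "GT",
          "0|1", "1|1", "0|0", sep = "\t")
  )
  writeLines(lines, path)
  path
}

# a small simulated panel of inbred lines, cached per session
panel_cache <- new.env(parent = emptyenv())
small_panel <- function(n_lines = 40, n_markers = 600, seed = 42) {
  key <- paste(n_lines, n_markers, seed, sep = "_")
  if (is.null(panel_cache[[key]])) {
    panel_cache[[key]] <- simulate_inbred_panel(
      n_lines = n_lines, n_markers = n_markers, seed = seed
    )$lines
  }
  panel_cache[[key]]
}

# brute-force additive kinship: double loop over individual pairs
loop_additive_kinship <- function(G) {
  p <- colMeans(G$calls + 1) / 2
  W <- sweep(G$calls + 1, 2, 2 * p)
  n <- nrow(W)
  denom <- 2 * sum(p * (1 - p))
  A <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    A[i, j] <- sum(W[i, ] * W[j, ]) / denom
  }
  dimnames(A) <- list(rownames(G$calls), rownames(G$calls))
  A
}

# brute-force dominance kinship
loop_dominance_kinship <- function(G) {
  q <- colMeans(G$calls + 1) / 2
  p <- 1 - q
  n <- nrow(G$calls)
  m <- ncol(G$calls)
  Wd <- matrix(0, n, m)
  for (i in seq_len(n)) for (k in seq_len(m)) {
    g <- G$calls[i, k]
    Wd[i, k] <- if (g == -1L) -2 * p[k]^2 else if (g == 0L) 2 * p[k] * q[k] else -2 * q[k]^2
  }
  denom <- sum((2 * p * q)^2)
  D <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    D[i, j] <- sum(Wd[i, ] * Wd[j, ]) / denom
  }
  dimnames(D) <- list(rownames(G$calls), rownames(G$calls))
  D
}

# brute-force all-pairs LD pruning oracle: repeatedly find the first
# offending pair in scan order and drop its later marker
bruteforce_ld_prune <- function(G, max_r2, window_bp) {
  keep <- seq_len(ncol(G$calls))
  repeat {
    offender <- NULL
    for (a in seq_along(keep)) {
      for (b in seq_along(keep)) {
        if (b <= a) next
        i <- keep[a]; j <- keep[b]
        if (G$markers$chrom[i] != G$markers$chrom[j]) next
        if (abs(G$markers$pos[j] - G$markers$pos[i]) > window_bp) next
        r2 <- hybridgs:::pairwise_r2(G$calls[, i], G$calls[, j])
        if (r2 > max_r2) { offender <- c(a, b); break }
      }
      if (!is.null(offender)) break
    }
    if (is.null(offender)) break
    keep <- keep[-offender[2]]
  }
  keep
}

# grid-search profile REML oracle over the variance ratio
grid_reml_oracle <- function(y, K, grid = seq(-10, 10, length.out = 4001)) {
  n <- length(y)
  X <- matrix(1, n, 1)
  eg <- eigen(K, symmetric = TRUE)
  d <- pmax(eg$values, 0)
  ys <- crossprod(eg$vectors, y)
  Xs <- crossprod(eg$vectors, X)
  ll <- vapply(grid, function(loglam) {
    lam <- exp(loglam)
    w <- 1 / (lam * d + 1)
    XtWX <- crossprod(Xs, Xs * w)
    b <- solve(XtWX, crossprod(Xs, ys * w))
    r <- ys - Xs %*% b
    s2e <- sum(w * r^2) / (n - 1)
    -0.5 * ((n - 1) * log(s2e) + sum(log(lam * d + 1)) +
              determinant(XtWX, logarithm = TRUE)$modulus + (n - 1))
  }, numeric(1))
  lam <- exp(grid[which.max(ll)])
  w <- 1 / (lam * d + 1)
  XtWX <- crossprod(Xs, Xs * w)
  b <- solve(XtWX, crossprod(Xs, ys * w))
  r <- ys - Xs %*% b
  s2e <- sum(w * r^2) / (n - 1)
  c(sigma2_A = lam * s2e, sigma2_e = s2e)
}
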