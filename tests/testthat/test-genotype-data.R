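test_that("VCF reading codes alt-allele dosage and handles missing and multiallelic sites", {
  path <- write_toy_vcf(tempfile(fileext = ".vcf"))
  G <- read_vcf(path)
  # triallelic v3 dropped
  expect_equal(ncol(G$calls), 4L)
  expect_equal(G$markers$id, c("v1", "v2", "v4", "v5"))
  # 0/0, 0/1, 1/1 -> -1, 0, +1
  expect_equal(unname(G$calls[, "v1"]), c(-1L, 0L, 1L))
  # ./. -> NA
  expect_true(is.na(G$calls["s1", "v2"]))
  # phased GTs read like unphased
  expect_equal(unname(G$calls[, "v5"]), c(0L, 1L, -1L))
  expect_error(read_vcf(path, biallelic_only = FALSE), "multiallelic")
  expect_error(read_vcf(tempfile(fileext = ".vcf")), "cannot read")
})

test_that("genotype TSV round-trips", {
  G <- toy_genotypes()
  path <- tempfile(fileext = ".tsv")
  write_genotype_tsv(G, path)
  G2 <- read_genotype_tsv(path)
  expect_equal(G2$calls, G$calls)
  expect_equal(G2$markers$pos, G$markers$pos)
})

test_that("MAF filter uses the folded non-missing allele frequency", {
  calls <- cbind(
    kept = c(1L, 1L, 1L, 1L, 0L),     # MAF = 0.1
    mono = c(1L, 1L, 1L, 1L, 1L),     # MAF = 0
    rare = c(1L, 1L, 1L, 1L, 1L)
  )
  rare_with_missing <- c(0L, 1L, 1L, NA, 1L)  # MAF = 1/8 on non-missing
  calls[, "rare"] <- rare_with_missing
  rownames(calls) <- paste0("s", 1:5)
  G <- genotype_matrix(calls)
  out <- filter_maf(G, 0.05)
  expect_setequal(colnames(out$genotypes$calls), c("kept", "rare"))
  expect_equal(out$report$removed_by_rule[["maf"]], 1L)
  # min_maf = 0 keeps everything
  expect_equal(ncol(filter_maf(G, 0)$genotypes$calls), 3L)
  expect_error(filter_maf(genotype_matrix(calls[, "mono", drop = FALSE]), 0.05),
               "all markers removed")
})

test_that("missingness filter removes markers above the threshold only", {
  calls <- matrix(0L, 10, 3, dimnames = list(paste0("s", 1:10), NULL))
  calls[, 1] <- rep(c(1L, -1L), 5)
  calls[1:2, 2] <- NA          # 20% missing
  calls[1, 3] <- NA            # 10% missing
  calls[3:10, 2] <- rep(c(1L, -1L), 4)
  calls[2:10, 3] <- rep(c(1L, -1L, 0L), 3)
  G <- genotype_matrix(calls)
  out <- filter_missing(G, 0.1)
  expect_equal(colnames(out$genotypes$calls), c("m1", "m3"))
  # threshold 1 is the identity
  expect_equal(ncol(filter_missing(G, 1)$genotypes$calls), 3L)
})

test_that("heterozygote-excess filter is strict at the boundary", {
  calls <- cbind(
    excess = c(rep(0L, 30), rep(1L, 40), rep(-1L, 30)),   # 30% het
    boundary = c(rep(0L, 25), rep(1L, 40), rep(-1L, 35)), # 25% het exactly
    allhom = rep(c(1L, -1L), 50)
  )
  rownames(calls) <- paste0("s", 1:100)
  G <- genotype_matrix(calls)
  out <- filter_het_excess(G, 0.25)
  expect_setequal(colnames(out$genotypes$calls), c("boundary", "allhom"))
})

test_that("LD pruning keeps the earlier marker and matches the brute-force oracle", {
  # two identical markers 500 bp apart -> second removed
  calls <- cbind(a = c(1L, -1L, 1L, -1L, 0L, 1L), b = c(1L, -1L, 1L, -1L, 0L, 1L))
  rownames(calls) <- paste0("s", 1:6)
  G <- genotype_matrix(calls, data.frame(id = c("a", "b"), chrom = "chr1",
                                         pos = c(100L, 600L)))
  out <- ld_prune(G, 0.95, 1000)
  expect_equal(colnames(out$genotypes$calls), "a")
  # same pair 1500 bp apart with a 1000 bp window -> both kept
  G2 <- genotype_matrix(calls, data.frame(id = c("a", "b"), chrom = "chr1",
                                          pos = c(100L, 1600L)))
  expect_equal(ncol(ld_prune(G2, 0.95, 1000)$genotypes$calls), 2L)
  # unsorted input errors
  G3 <- genotype_matrix(calls, data.frame(id = c("a", "b"), chrom = "chr1",
                                          pos = c(600L, 100L)))
  expect_error(ld_prune(G3, 0.95, 1000), "sorted")

  # 6-marker toy chromosome vs brute-force all-pairs oracle
  set.seed(7)
  base <- sample(c(-1L, 0L, 1L), 30, replace = TRUE)
  calls6 <- cbind(base,
                  base,                                  # r2 = 1 with col 1
                  sample(c(-1L, 0L, 1L), 30, TRUE),
                  base * -1L,                            # r2 = 1 with col 1
                  sample(c(-1L, 0L, 1L), 30, TRUE),
                  sample(c(-1L, 0L, 1L), 30, TRUE))
  rownames(calls6) <- paste0("s", 1:30)
  colnames(calls6) <- paste0("m", 1:6)
  G6 <- genotype_matrix(calls6, data.frame(
    id = paste0("m", 1:6), chrom = "chr1",
    pos = c(100L, 400L, 700L, 900L, 1600L, 2000L)
  ))
  out6 <- ld_prune(G6, 0.5, 1000)
  oracle <- bruteforce_ld_prune(G6, 0.5, 1000)
  expect_equal(colnames(out6$genotypes$calls), paste0("m", oracle))
  # post-check invariant: no retained pair within the window exceeds max_r2
  kept <- out6$genotypes
  for (i in seq_len(ncol(kept$calls))) for (j in seq_len(ncol(kept$calls))) {
    if (j <= i) next
    if (kept$markers$chrom[i] != kept$markers$chrom[j]) next
    if (kept$markers$pos[j] - kept$markers$pos[i] > 1000) next
    expect_lte(hybridgs:::pairwise_r2(kept$calls[, i], kept$calls[, j]), 0.5)
  }
})

test_that("filters are idempotent and the pipeline report is consistent", {
  G <- small_panel()
  set.seed(9)
  calls <- G$calls
  calls[sample(length(calls), length(calls) * 0.05)] <- NA
  Gm <- genotype_matrix(calls, G$markers)
  for (f in list(function(g) filter_maf(g, 0.05),
                 function(g) filter_missing(g, 0.1),
                 function(g) filter_het_excess(g, 0.25))) {
    once <- f(Gm)$genotypes
    twice <- f(once)$genotypes
    expect_equal(twice$calls, once$calls)
  }
  out <- filter_genotypes(Gm, seed = 3)
  rep <- out$report
  expect_equal(rep$markers_out, rep$markers_in - sum(rep$removed_by_rule))
  expect_equal(rep$rule_order, c("missing", "maf", "het_excess", "ld_prune"))
  expect_equal(ncol(out$genotypes$calls), rep$markers_out)
  expect_false(anyNA(out$genotypes$calls))
  # byte-identical rerun
  out2 <- filter_genotypes(Gm, seed = 3)
  expect_identical(out$genotypes$calls, out2$genotypes$calls)
})

test_that("imputation fills all cells, is deterministic, and recovers masked homozygous calls", {
  # mode rule on a toy marker
  G <- genotype_matrix(matrix(c(1L, 1L, NA), 3, 1,
                              dimnames = list(paste0("s", 1:3), "m1")))
  expect_equal(unname(impute_missing(G)$calls[3, 1]), 1L)
  # complete matrix returned unchanged
  Gc <- small_panel()
  expect_identical(impute_missing(Gc)$calls, Gc$calls)
  # all-missing marker errors with its name
  Gb <- genotype_matrix(matrix(c(1L, NA, NA, NA), 2, 2,
                               dimnames = list(c("s1", "s2"), c("ok", "bad"))))
  expect_error(impute_missing(Gb), "bad")
  # masking experiment: >= 80% of masked homozygous cells recovered
  # masking experiment at low MAF (~0.1), where the marker mode is the major
  # homozygote for the large majority of lines
  maf <- pmin(hybridgs:::marker_allele_freq(Gc),
              1 - hybridgs:::marker_allele_freq(Gc))
  low <- maf >= 0.05 & maf <= 0.15
  G01 <- Gc[, low]
  set.seed(11)
  rates <- replicate(20, {
    calls <- G01$calls
    masked <- calls
    masked[sample(length(calls), round(0.1 * length(calls)))] <- NA
    ok <- colSums(is.na(masked)) < nrow(masked)
    truth <- calls[, ok, drop = FALSE]
    masked <- masked[, ok, drop = FALSE]
    imp <- impute_missing(genotype_matrix(masked, G01$markers[ok, ]))
    cells <- which(is.na(masked) & truth != 0L)  # masked homozygous cells
    mean(imp$calls[cells] == truth[cells])
  })
  expect_gte(mean(rates), 0.8)
})

test_that("homozygosity and its selfing expectation agree", {
  G <- genotype_matrix(rbind(hom = c(1L, -1L, 1L, 1L), het = c(0L, 0L, 0L, 0L)))
  h <- homozygosity(G)
  expect_equal(unname(h), c(1, 0))
  expect_true(all(homozygosity(small_panel()) >= 0 &
                    homozygosity(small_panel()) <= 1))
  # closed form
  expect_identical(expected_homozygosity(4), 0.9375)
  expect_identical(expected_homozygosity(1), 0.5)
  expect_identical(expected_homozygosity(0), 0)
  expect_error(expected_homozygosity(-1), ">= 0")
  # strictly increasing toward 1
  eh <- expected_homozygosity(0:20)
  expect_true(all(diff(eh) > 0))
  expect_lt(abs(eh[21] - 1), 1e-5)
})
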