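## Genomic relationship matrices. A follows VanRaden method 1; D follows the
## classical dominance-deviation (Vitezica-style) parameterization. Allele
## frequencies are taken from the supplied matrix unless `freq` overrides them
## (used for across-population prediction, where training-population
## frequencies must be applied to the combined matrix).

kinship_freq <- function(G, freq = NULL) {
  if (is.null(freq)) freq <- marker_allele_freq(G)
  stopifnot(length(freq) == ncol(G$calls))
  freq
}

#' Additive genomic relationship matrix (VanRaden method 1)
#'
#' `A = W W' / (2 * sum(p * (1 - p)))` where `W` is the alt-allele dosage
#' matrix (coded call + 1) column-centered by `2p`.
#'
#' @param G fully imputed [genotype_matrix()], monomorphic markers excluded
#' @param freq optional per-marker alt-allele frequencies to center/scale by
#'   (defaults to frequencies computed from `G`; supply training-population
#'   frequencies for across-population work)
#' @return n x n symmetric matrix with individual IDs as dimnames and
#'   attributes `flavor = "additive"` and `freq_source`
#' @export
additive_kinship <- function(G, freq = NULL) {
  p <- kinship_freq(G, freq)
  denom <- 2 * sum(p * (1 - p))
  if (denom <= 0) stop("all markers monomorphic: additive kinship undefined")
  W <- sweep(G$calls + 1, 2, 2 * p)
  A <- tcrossprod(W) / denom
  dimnames(A) <- list(individuals(G), individuals(G))
  attr(A, "flavor") <- "additive"
  attr(A, "freq_source") <- if (is.null(freq)) "self" else "supplied"
  A
}

#' Dominance genomic relationship matrix
#'
#' Dominance-deviation coding per genotype class
#' \{aa, Aa, AA\} -> \{-2p^2, 2pq, -2q^2\} (q = alt-allele frequency,
#' p = 1 - q under the orientation used here; the labels are symmetric), with
#' `D = Wd Wd' / sum((2pq)^2)`.
#'
#' @inheritParams additive_kinship
#' @return n x n symmetric matrix, attribute `flavor = "dominance"`
#' @export
dominance_kinship <- function(G, freq = NULL) {
  q <- kinship_freq(G, freq)   # alt-allele frequency
  p <- 1 - q
  denom <- sum((2 * p * q)^2)
  if (denom <= 0) stop("all markers monomorphic: dominance kinship undefined")
  calls <- G$calls
  Wd <- matrix(0, nrow(calls), ncol(calls))
  for (k in seq_len(ncol(calls))) {
    code <- c(-2 * p[k]^2, 2 * p[k] * q[k], -2 * q[k]^2) # aa, Aa, AA
    Wd[, k] <- code[calls[, k] + 2L]
  }
  D <- tcrossprod(Wd) / denom
  dimnames(D) <- list(individuals(G), individuals(G))
  attr(D, "flavor") <- "dominance"
  attr(D, "freq_source") <- if (is.null(freq)) "self" else "supplied"
  D
}

#' Heterozygosity design matrix
#'
#' Indicator coding \{0, 1, 0\} for \{aa, Aa, AA\}; used as the dominance
#' design in marker-effect models (Bayes B / Bayesian Lasso with additive
#' plus dominant effects).  Centering keeps the model intercept at the
#' population mean.
#'
#' @param G fully imputed [genotype_matrix()]
#' @param center center columns by their means (default `TRUE`)
#' @return individuals x markers numeric matrix
#' @export
heterozygosity_design <- function(G, center = TRUE) {
  H <- (G$calls == 0L) * 1
  dimnames(H) <- dimnames(G$calls)
  if (center) H <- sweep(H, 2, colMeans(H))
  H
}

#' Write a kinship matrix as TSV with an ID header
#' @param K kinship matrix (as from [additive_kinship()])
#' @param path output path; flavor is recorded in a sidecar `<path>.meta.json`
#' @export
write_kinship_tsv <- function(K, path) {
  d <- data.frame(id = rownames(K), as.data.frame(K, check.names = FALSE),
                  check.names = FALSE)
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  meta <- sprintf('{"flavor": "%s", "freq_source": "%s"}',
                  attr(K, "flavor"), attr(K, "freq_source"))
  writeLines(meta, paste0(path, ".meta.json"))
}
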