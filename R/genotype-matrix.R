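#' Construct a genotype matrix object
#'
#' A `GenotypeMatrix` holds biallelic SNP calls for a set of individuals,
#' coded as \code{-1} (homozygous aa), \code{0} (heterozygous Aa),
#' \code{+1} (homozygous AA), with \code{NA} for missing calls.  The coding
#' follows the alt-allele dosage convention: dosage 0 -> -1, 1 -> 0, 2 -> +1.
#' The aa/AA labels are abstract; only consistency across modules matters,
#' since the orientation cancels in every downstream statistic.
#'
#' @param calls integer/numeric matrix, individuals x markers, values in
#'   \{-1, 0, 1, NA\}.  Rownames are individual IDs, colnames marker IDs
#'   (supplied via `markers$id` if absent).
#' @param markers data.frame with columns `id`, `chrom`, `pos` (1-based bp),
#'   and optionally `ref`, `alt`.  One row per column of `calls`.
#' @return An object of class `GenotypeMatrix`: a list with elements
#'   `calls` (the coded matrix) and `markers` (the marker metadata).
#' @export
genotype_matrix <- function(calls, markers = NULL) {
  calls <- as.matrix(calls)
  storage.mode(calls) <- "integer"
  if (is.null(markers)) {
    if (is.null(colnames(calls))) {
      colnames(calls) <- paste0("m", seq_len(ncol(calls)))
    }
    markers <- data.frame(
      id = colnames(calls),
      chrom = "chr1",
      pos = seq_len(ncol(calls)),
      stringsAsFactors = FALSE
    )
  }
  markers <- as.data.frame(markers, stringsAsFactors = FALSE)
  stopifnot(all(c("id", "chrom", "pos") %in% names(markers)))
  if (nrow(markers) != ncol(calls)) {
    stop("markers must have one row per column of calls")
  }
  if (is.null(colnames(calls))) colnames(calls) <- markers$id
  if (is.null(rownames(calls))) {
    rownames(calls) <- paste0("line", seq_len(nrow(calls)))
  }
  if (anyDuplicated(rownames(calls))) stop("duplicate individual IDs")
  if (anyDuplicated(markers$id)) stop("duplicate marker IDs")
  if (any(markers$pos < 1)) stop("positions must be >= 1 (1-based)")
  bad <- calls[!is.na(calls)]
  if (length(bad) && !all(bad %in% c(-1L, 0L, 1L))) {
    stop("non-missing calls must be in {-1, 0, 1}")
  }
  structure(list(calls = calls, markers = markers), class = "GenotypeMatrix")
}

#' @export
print.GenotypeMatrix <- function(x, ...) {
  cat(sprintf(
    "GenotypeMatrix: %d individuals x %d markers (%.2f%% missing)\n",
    nrow(x$calls), ncol(x$calls), 100 * mean(is.na(x$calls))
  ))
  invisible(x)
}

#' @export
dim.GenotypeMatrix <- function(x) dim(x$calls)

#' Individual IDs of a genotype matrix
#' @param G a `GenotypeMatrix`
#' @return character vector of individual IDs
#' @export
individuals <- function(G) rownames(G$calls)

#' Subset a genotype matrix
#' @param x a `GenotypeMatrix`
#' @param i individual index/names
#' @param j marker index/names
#' @param ... ignored
#' @export
`[.GenotypeMatrix` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$calls))
  if (missing(j)) j <- seq_len(ncol(x$calls))
  calls <- x$calls[i, j, drop = FALSE]
  jj <- match(colnames(calls), x$markers$id)
  genotype_matrix(calls, x$markers[jj, , drop = FALSE])
}

#' Read a VCF into a coded genotype matrix
#'
#' Diploid GT fields are mapped to alt-allele dosage and recoded
#' \{0, 1, 2\} -> \{-1, 0, +1\}; missing GTs become `NA`.  Phasing is
#' ignored.  Sites with more than one ALT allele are dropped when
#' `biallelic_only` is `TRUE` (the default), otherwise reading stops with an
#' error on the first multiallelic site.
#'
#' @param path path to a VCF file (plain or bgzipped)
#' @param biallelic_only drop multiallelic sites rather than erroring
#' @return a [genotype_matrix()]
#' @export
read_vcf <- function(path, biallelic_only = TRUE) {
  if (!file.exists(path)) stop("cannot read VCF: ", path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  multi <- grepl(",", fix[, "ALT"]) | is.na(fix[, "ALT"])
  if (any(multi) && !biallelic_only) stop("multiallelic sites present")
  keep <- !multi
  if (!any(keep)) stop("no biallelic SNPs in ", path)
  gt <- vcfR::extract.gt(v, element = "GT")
  gt <- gt[keep, , drop = FALSE]
  fix <- fix[keep, , drop = FALSE]
  # alt-allele dosage from unphased or phased diploid GT strings
  code <- function(g) {
    out <- rep(NA_integer_, length(g))
    g <- gsub("|", "/", g, fixed = TRUE)
    out[g %in% "0/0"] <- -1L
    out[g %in% c("0/1", "1/0")] <- 0L
    out[g %in% "1/1"] <- 1L
    out
  }
  calls <- t(matrix(code(gt), nrow = nrow(gt)))
  rownames(calls) <- colnames(gt)
  ids <- fix[, "ID"]
  noid <- is.na(ids) | ids == "."
  ids[noid] <- paste0(fix[noid, "CHROM"], "_", fix[noid, "POS"])
  colnames(calls) <- ids
  markers <- data.frame(
    id = ids, chrom = fix[, "CHROM"], pos = as.integer(fix[, "POS"]),
    ref = fix[, "REF"], alt = fix[, "ALT"], stringsAsFactors = FALSE
  )
  genotype_matrix(calls, markers)
}

#' Read a plain-text genotype table
#'
#' Expects a TSV with columns `id`, `chrom`, `pos` followed by one column per
#' individual; cells in \{-1, 0, 1, NA\} (rows are markers).
#'
#' @param path path to TSV
#' @return a [genotype_matrix()]
#' @export
read_genotype_tsv <- function(path) {
  d <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  meta <- c("id", "chrom", "pos")
  stopifnot(all(meta %in% names(d)))
  extra <- intersect(c("ref", "alt"), names(d))
  calls <- t(as.matrix(d[, setdiff(names(d), c(meta, extra)), drop = FALSE]))
  colnames(calls) <- d$id
  genotype_matrix(calls, d[, c(meta, extra), drop = FALSE])
}

#' Write a genotype matrix as a plain-text table
#' @param G a `GenotypeMatrix`
#' @param path output TSV path
#' @export
write_genotype_tsv <- function(G, path) {
  d <- cbind(G$markers, as.data.frame(t(G$calls), check.names = FALSE))
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Per-individual homozygosity
#'
#' Fraction of homozygous calls (\code{-1} or \code{+1}) per individual,
#' computed over non-missing calls.  For lines derived by repeated selfing
#' this is compared against [expected_homozygosity()].
#'
#' @param G a `GenotypeMatrix`
#' @return named numeric vector in \[0, 1\], one value per individual
#' @export
homozygosity <- function(G) {
  apply(G$calls, 1, function(x) mean(x != 0, na.rm = TRUE))
}

#' Expected homozygosity after selfing
#'
#' For a locus starting fully heterozygous, heterozygosity halves each selfing
#' generation, so expected homozygosity after `t` generations is
#' \eqn{1 - (1/2)^t}: 0.9375 after four generations of single seed descent.
#'
#' @param selfing_generations non-negative integer number of generations
#' @return expected homozygous fraction
#' @export
expected_homozygosity <- function(selfing_generations) {
  if (any(selfing_generations < 0)) stop("selfing_generations must be >= 0")
  1 - 0.5^selfing_generations
}
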