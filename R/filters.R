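## Marker QC filters. Each filter returns list(genotypes, report) where the
## report records counts relative to its own input, so a pipeline of filters
## composes into a sequential FilterReport.

new_filter_report <- function(markers_in, removed_by_rule) {
  removed_by_rule <- unlist(removed_by_rule)
  structure(list(
    markers_in = markers_in,
    markers_out = markers_in - sum(removed_by_rule),
    removed_by_rule = removed_by_rule,
    rule_order = names(removed_by_rule)
  ), class = "FilterReport")
}

#' @export
print.FilterReport <- function(x, ...) {
  cat(sprintf("FilterReport: %d -> %d markers\n", x$markers_in, x$markers_out))
  for (r in x$rule_order) {
    cat(sprintf("  %-12s removed %d\n", r, x$removed_by_rule[[r]]))
  }
  invisible(x)
}

marker_subset <- function(G, keep, rule) {
  removed <- setNames(list(sum(!keep)), rule)
  report <- new_filter_report(ncol(G$calls), removed)
  if (!any(keep)) stop("all markers removed by rule '", rule, "'")
  list(
    genotypes = genotype_matrix(G$calls[, keep, drop = FALSE],
                                G$markers[keep, , drop = FALSE]),
    report = report
  )
}

## alt-allele frequency per marker from coded calls; MAF = min(p, 1-p)
marker_allele_freq <- function(G) {
  colMeans(G$calls + 1L, na.rm = TRUE) / 2
}

#' Filter markers on minor allele frequency
#'
#' MAF is computed from non-missing calls as the folded alt-allele frequency
#' `(2*count(+1) + count(0)) / (2*non-missing)`.  Markers with MAF strictly
#' below `min_maf` are removed.
#'
#' @param G a [genotype_matrix()]
#' @param min_maf minimum minor allele frequency in \[0, 0.5\]
#' @return list with elements `genotypes` (filtered matrix) and `report`
#' @export
filter_maf <- function(G, min_maf = 0.05) {
  stopifnot(min_maf >= 0, min_maf <= 0.5)
  p <- marker_allele_freq(G)
  maf <- pmin(p, 1 - p)
  marker_subset(G, maf >= min_maf, "maf")
}

#' Filter markers on missing-data fraction
#'
#' Markers whose fraction of missing calls exceeds `max_missing_fraction`
#' are removed.
#'
#' @param G a [genotype_matrix()]
#' @param max_missing_fraction maximum tolerated missing fraction in \[0, 1\]
#' @return list with elements `genotypes` and `report`
#' @export
filter_missing <- function(G, max_missing_fraction = 0.1) {
  stopifnot(max_missing_fraction >= 0, max_missing_fraction <= 1)
  miss <- colMeans(is.na(G$calls))
  marker_subset(G, miss <= max_missing_fraction, "missing")
}

#' Filter markers with excess heterozygosity
#'
#' In a diploidized allopolyploid, markers with too many heterozygotes are
#' likely not subgenome-specific.  Markers whose heterozygote frequency among
#' non-missing calls is strictly greater than `max_het` are removed; the
#' boundary value is retained.
#'
#' @param G a [genotype_matrix()]
#' @param max_het maximum heterozygote frequency (default 0.25)
#' @return list with elements `genotypes` and `report`
#' @export
filter_het_excess <- function(G, max_het = 0.25) {
  stopifnot(max_het >= 0, max_het <= 1)
  het <- apply(G$calls, 2, function(x) mean(x == 0, na.rm = TRUE))
  het[is.nan(het)] <- 0
  marker_subset(G, het <= max_het, "het_excess")
}

#' Filter markers on unanchored chromosomes
#'
#' Removes markers whose chromosome label matches `pattern` (markers on
#' unanchored scaffolds have ambiguous chromosomal location).
#'
#' @param G a [genotype_matrix()]
#' @param pattern regular expression matched against chromosome labels
#' @return list with elements `genotypes` and `report`
#' @export
filter_unanchored <- function(G, pattern = "^(scaffold|chrUn|un)") {
  keep <- !grepl(pattern, G$markers$chrom, ignore.case = TRUE)
  marker_subset(G, keep, "unanchored")
}

## r^2 between two coded-call vectors over pairwise-complete observations.
## Pairs with < 3 complete observations or zero variance count as r^2 = 0.
pairwise_r2 <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < 3) return(0)
  x <- x[ok]; y <- y[ok]
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(0)
  stats::cor(x, y)^2
}

#' Window-based LD pruning
#'
#' Scans each chromosome left to right.  A marker is removed when its squared
#' genotype correlation with any already-retained marker within `window_bp`
#' exceeds `max_r2`; i.e. the earlier-positioned marker of a high-LD pair is
#' kept.  Markers must be sorted by (chromosome, position).
#'
#' @param G a [genotype_matrix()]
#' @param max_r2 maximum tolerated squared correlation (default 0.95)
#' @param window_bp window size in base pairs (default 1000)
#' @return list with elements `genotypes` and `report`
#' @export
ld_prune <- function(G, max_r2 = 0.95, window_bp = 1000) {
  m <- G$markers
  ord <- order(m$chrom, m$pos)
  if (!identical(ord, seq_len(nrow(m)))) {
    stop("markers must be sorted by (chromosome, position) before LD pruning")
  }
  keep <- rep(TRUE, ncol(G$calls))
  for (chr in unique(m$chrom)) {
    idx <- which(m$chrom == chr)
    retained <- integer(0)
    for (j in idx) {
      # only retained markers within the window need checking
      near <- retained[m$pos[j] - m$pos[retained] <= window_bp]
      drop <- FALSE
      for (i in near) {
        if (pairwise_r2(G$calls[, i], G$calls[, j]) > max_r2) {
          drop <- TRUE
          break
        }
      }
      if (drop) keep[j] <- FALSE else retained <- c(retained, j)
    }
  }
  marker_subset(G, keep, "ld_prune")
}

#' Impute missing genotype calls
#'
#' Simple deterministic per-marker imputation: `mode` replaces missing calls
#' with the most frequent observed call at that marker (ties broken toward
#' the smaller code); `marker_mean_rounded` uses the observed marker mean
#' rounded to the nearest valid code.  Adequate at the low missingness this
#' pipeline tolerates (<= 10% per marker after [filter_missing()]).
#'
#' @param G a [genotype_matrix()]
#' @param method `"mode"` or `"marker_mean_rounded"`
#' @param seed integer seed (recorded for reproducibility; both methods are
#'   in fact deterministic)
#' @return a fully observed [genotype_matrix()]
#' @export
impute_missing <- function(G, method = c("mode", "marker_mean_rounded"),
                           seed = 1L) {
  method <- match.arg(method)
  calls <- G$calls
  nmiss <- colSums(is.na(calls))
  if (any(nmiss == nrow(calls))) {
    stop("marker(s) with all calls missing: ",
         paste(colnames(calls)[nmiss == nrow(calls)], collapse = ", "))
  }
  for (j in which(nmiss > 0)) {
    x <- calls[, j]
    obs <- x[!is.na(x)]
    fill <- if (method == "mode") {
      tab <- table(factor(obs, levels = c(-1L, 0L, 1L)))
      as.integer(names(tab)[which.max(tab)])
    } else {
      as.integer(max(-1L, min(1L, round(mean(obs)))))
    }
    calls[is.na(x), j] <- fill
  }
  out <- genotype_matrix(calls, G$markers)
  attr(out, "impute_seed") <- seed
  out
}

#' Run the full marker QC pipeline
#'
#' Applies, in order: missingness filter, MAF filter, heterozygote-excess
#' filter, LD pruning, and imputation.  The order is fixed and recorded in the
#' combined report; rerunning with the same configuration reproduces identical
#' output.
#'
#' @param G a [genotype_matrix()]
#' @param min_maf,max_missing,max_het,ld_r2,ld_window filter thresholds
#' @param impute_method passed to [impute_missing()]
#' @param seed passed to [impute_missing()]
#' @return list with elements `genotypes` (filtered, imputed) and `report`
#' @export
filter_genotypes <- function(G, min_maf = 0.05, max_missing = 0.1,
                             max_het = 0.25, ld_r2 = 0.95, ld_window = 1000,
                             impute_method = "mode", seed = 1L) {
  markers_in <- ncol(G$calls)
  removed <- list()
  s <- filter_missing(G, max_missing)
  removed$missing <- s$report$removed_by_rule[["missing"]]
  s <- filter_maf(s$genotypes, min_maf)
  removed$maf <- s$report$removed_by_rule[["maf"]]
  s <- filter_het_excess(s$genotypes, max_het)
  removed$het_excess <- s$report$removed_by_rule[["het_excess"]]
  s <- ld_prune(s$genotypes, ld_r2, ld_window)
  removed$ld_prune <- s$report$removed_by_rule[["ld_prune"]]
  G2 <- impute_missing(s$genotypes, impute_method, seed)
  list(genotypes = G2, report = new_filter_report(markers_in, removed))
}
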