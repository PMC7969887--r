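## Breeding-population simulator: phased diploid founders, recurrent random
## intercrossing, single seed descent, and additive + dominance trait
## architectures with full ground truth. Everything is seeded and
## deterministic given its configuration.

new_phased_population <- function(H1, H2, markers, ids) {
  rownames(H1) <- rownames(H2) <- ids
  colnames(H1) <- colnames(H2) <- markers$id
  structure(list(H1 = H1, H2 = H2, markers = markers), class = "PhasedPopulation")
}

#' @export
print.PhasedPopulation <- function(x, ...) {
  cat(sprintf("PhasedPopulation: %d individuals x %d markers\n",
              nrow(x$H1), ncol(x$H1)))
  invisible(x)
}

#' Collapse a phased population to coded genotype calls
#' @param pop a `PhasedPopulation`
#' @return a [genotype_matrix()] with calls `H1 + H2 - 1` in \{-1, 0, 1\}
#' @export
as_genotype_matrix <- function(pop) {
  genotype_matrix(pop$H1 + pop$H2 - 1L, pop$markers)
}

#' Simulate outbred diploid founders
#'
#' Biallelic markers with alt-allele frequencies drawn uniformly on
#' \[0.1, 0.9\], placed with uniform spacing on `n_chrom` chromosomes;
#' founder haplotypes are sampled at those frequencies, so heterozygosity is
#' at Hardy-Weinberg rates.  `fully_heterozygous = TRUE` instead makes every
#' founder heterozygous at every locus (the textbook starting point for
#' inbreeding-expectation checks).
#'
#' @param n_founders number of founders
#' @param n_markers number of markers
#' @param n_chrom number of chromosomes (default 7)
#' @param chrom_bp physical length per chromosome in bp (default 1e6)
#' @param seed integer seed
#' @param fully_heterozygous force Aa at every locus of every founder
#' @return a `PhasedPopulation`
#' @export
simulate_founders <- function(n_founders, n_markers, n_chrom = 7,
                              chrom_bp = 1e6, seed = 1L,
                              fully_heterozygous = FALSE) {
  per <- ceiling(n_markers / n_chrom)
  chrom <- rep(paste0("chr", seq_len(n_chrom)), each = per)[seq_len(n_markers)]
  pos <- unlist(lapply(table(chrom)[unique(chrom)], function(k) {
    as.integer(round(seq(1, chrom_bp, length.out = k)))
  }), use.names = FALSE)
  markers <- data.frame(
    id = sprintf("m%05d", seq_len(n_markers)), chrom = chrom, pos = pos,
    stringsAsFactors = FALSE
  )
  with_seed(seed, {
    freq <- stats::runif(n_markers, 0.1, 0.9)
    if (fully_heterozygous) {
      H1 <- matrix(1L, n_founders, n_markers)
      H2 <- matrix(0L, n_founders, n_markers)
    } else {
      H1 <- matrix(stats::rbinom(n_founders * n_markers, 1,
                                 rep(freq, each = n_founders)),
                   n_founders, n_markers)
      H2 <- matrix(stats::rbinom(n_founders * n_markers, 1,
                                 rep(freq, each = n_founders)),
                   n_founders, n_markers)
    }
    pop <- new_phased_population(H1, H2, markers,
                                 sprintf("F%03d", seq_len(n_founders)))
    attr(pop, "freq") <- freq
    pop
  })
}

## One recombinant gamete from individual `i`: per chromosome, Poisson
## crossovers (rate `morgans` per chromosome) at uniform genetic positions,
## independent assortment between chromosomes. Genetic position is taken
## proportional to physical position.
meiosis_gamete <- function(pop, i, chrom_index, morgans = 1) {
  m <- ncol(pop$H1)
  hap <- integer(m)
  for (ci in chrom_index) {
    nco <- stats::rpois(1, morgans)
    start <- stats::rbinom(1, 1, 0.5)
    if (nco == 0) {
      hap[ci$idx] <- start
    } else {
      xo <- sort(stats::runif(nco))
      seg <- findInterval(ci$relpos, xo)
      hap[ci$idx] <- (start + seg) %% 2
    }
  }
  ifelse(hap == 0, pop$H1[i, ], pop$H2[i, ])
}

chrom_index_of <- function(markers) {
  lapply(unique(markers$chrom), function(ch) {
    idx <- which(markers$chrom == ch)
    p <- markers$pos[idx]
    list(idx = idx, relpos = (p - min(p)) / max(1, diff(range(p))))
  })
}

#' Recurrent random intercrossing
#'
#' Each cycle draws `n_progeny` offspring; each offspring gets one
#' recombinant gamete from each of two distinct, uniformly sampled parents.
#'
#' @param pop a `PhasedPopulation`
#' @param cycles number of intercross cycles (0 returns the population
#'   unchanged)
#' @param n_progeny population size per cycle (default: current size)
#' @param morgans map length per chromosome in Morgans (default 1)
#' @param seed integer seed
#' @return a `PhasedPopulation`
#' @export
random_intercross <- function(pop, cycles, n_progeny = NULL, morgans = 1,
                              seed = 1L) {
  if (cycles == 0) return(pop)
  stopifnot(nrow(pop$H1) >= 2)
  if (is.null(n_progeny)) n_progeny <- nrow(pop$H1)
  ci <- chrom_index_of(pop$markers)
  with_seed(seed, {
    for (cy in seq_len(cycles)) {
      H1 <- matrix(0L, n_progeny, ncol(pop$H1))
      H2 <- H1
      for (j in seq_len(n_progeny)) {
        par <- sample.int(nrow(pop$H1), 2)
        H1[j, ] <- meiosis_gamete(pop, par[1], ci, morgans)
        H2[j, ] <- meiosis_gamete(pop, par[2], ci, morgans)
      }
      pop <- new_phased_population(H1, H2, pop$markers,
                                   sprintf("C%d_%03d", cy, seq_len(n_progeny)))
    }
    pop
  })
}

#' Single seed descent
#'
#' Each line is selfed for `generations` generations, keeping one offspring
#' per generation (per-locus gametes sampled Mendelianly with recombination).
#' `retained_het_fraction > 0` makes that fraction of loci immune to
#' fixation — a heterozygous parent transmits the heterozygote there —
#' a phenomenological stand-in for loci kept heterozygous by inbreeding
#' depression, which leaves realized homozygosity below the `1 - (1/2)^t`
#' expectation.
#'
#' @param pop a `PhasedPopulation` (each individual founds one line)
#' @param generations selfing generations (>= 0)
#' @param morgans map length per chromosome in Morgans
#' @param retained_het_fraction fraction of loci immune to fixation
#' @param seed integer seed
#' @return list with `lines` (a coded [genotype_matrix()], IDs `L001`, ...)
#'   and `phased` (the final `PhasedPopulation`)
#' @export
single_seed_descent <- function(pop, generations, morgans = 1,
                                retained_het_fraction = 0, seed = 1L) {
  stopifnot(generations >= 0)
  n <- nrow(pop$H1)
  m <- ncol(pop$H1)
  ci <- chrom_index_of(pop$markers)
  with_seed(seed, {
    immune <- if (retained_het_fraction > 0) {
      sample.int(m, round(retained_het_fraction * m))
    } else integer(0)
    H1 <- pop$H1
    H2 <- pop$H2
    cur <- pop
    for (g in seq_len(generations)) {
      N1 <- matrix(0L, n, m)
      N2 <- N1
      for (j in seq_len(n)) {
        N1[j, ] <- meiosis_gamete(cur, j, ci, morgans)
        N2[j, ] <- meiosis_gamete(cur, j, ci, morgans)
      }
      if (length(immune)) {
        was_het <- cur$H1[, immune, drop = FALSE] != cur$H2[, immune, drop = FALSE]
        N1[, immune][was_het] <- cur$H1[, immune, drop = FALSE][was_het]
        N2[, immune][was_het] <- cur$H2[, immune, drop = FALSE][was_het]
      }
      cur <- new_phased_population(N1, N2, pop$markers, rownames(pop$H1))
    }
    lines <- new_phased_population(cur$H1, cur$H2, pop$markers,
                                   sprintf("L%03d", seq_len(n)))
    list(lines = as_genotype_matrix(lines), phased = lines)
  })
}

#' Simulate an inbred-line panel (founders -> intercross -> SSD)
#'
#' Convenience wrapper reproducing the breeding geometry this package
#' targets: outbred founders, recurrent random intercrossing to mix their
#' genomes, then single seed descent to derive near-homozygous candidate
#' parent lines.
#'
#' @param n_lines number of inbred lines (default 105)
#' @param n_markers number of markers (default 2000)
#' @param n_founders number of founders (default 22)
#' @param intercross_cycles intercross cycles (default 3)
#' @param selfing_generations SSD generations (default 4)
#' @param n_chrom chromosomes (default 7)
#' @param retained_het_fraction passed to [single_seed_descent()]
#' @param seed integer seed
#' @return list with `lines` (coded [genotype_matrix()]) and `phased`
#' @export
simulate_inbred_panel <- function(n_lines = 105, n_markers = 2000,
                                  n_founders = 22, intercross_cycles = 3,
                                  selfing_generations = 4, n_chrom = 7,
                                  retained_het_fraction = 0, seed = 1L) {
  fo <- simulate_founders(n_founders, n_markers, n_chrom = n_chrom,
                          seed = sub_seed(seed, 1))
  ic <- random_intercross(fo, intercross_cycles, n_progeny = n_lines,
                          seed = sub_seed(seed, 2))
  single_seed_descent(ic, selfing_generations,
                      retained_het_fraction = retained_het_fraction,
                      seed = sub_seed(seed, 3))
}

#' Assign an additive + dominance trait architecture
#'
#' Samples QTL without replacement, draws additive effects from a normal
#' distribution and dominance effects as degree-of-dominance times
#' `|additive|` (degree ~ N(`dd_mean`, `dd_sd`)), then rescales each effect
#' vector so the realized additive and dominance variance components in the
#' reference population hit their targets exactly.  True genetic value is
#' `sum(additive * dosage) + sum(dominance * heterozygosity)`, matching the
#' \{-1,0,1\} / \{0,1,0\} model parameterization.
#'
#' @param G reference-population [genotype_matrix()] (fully observed)
#' @param n_qtl number of QTL
#' @param sigma2_A,sigma2_D target variance components (dominance may be 0)
#' @param dd_mean,dd_sd degree-of-dominance distribution (defaults 0.5, 0.25)
#' @param mu trait intercept
#' @param seed integer seed
#' @return a `SimTruth` list: `qtl` (marker indices), `qtl_id`,
#'   `add_effects`, `dom_effects`, `mu`, `gv` (true genetic values in `G`),
#'   `realized` variance components
#' @export
assign_trait_architecture <- function(G, n_qtl, sigma2_A, sigma2_D = 0,
                                      dd_mean = 0.5, dd_sd = 0.25, mu = 0,
                                      seed = 1L) {
  m <- ncol(G$calls)
  stopifnot(n_qtl <= m, sigma2_A >= 0, sigma2_D >= 0)
  with_seed(seed, {
    qtl <- sort(sample.int(m, n_qtl))
    a <- stats::rnorm(n_qtl)
    dd <- stats::rnorm(n_qtl, dd_mean, dd_sd)
    W <- G$calls[, qtl, drop = FALSE]
    H <- (W == 0L) * 1
    va <- stats::var(drop(W %*% a))
    if (sigma2_A > 0) {
      if (va <= 0) stop("no additive variance achievable (monomorphic QTL?)")
      a <- a * sqrt(sigma2_A / va)
    } else {
      a <- a * 0
    }
    d <- dd * abs(a)
    if (sigma2_D > 0) {
      vd <- stats::var(drop(H %*% d))
      if (vd <= 0) {
        # e.g. a fully homozygous reference population
        stop("dominance variance target unachievable: no heterozygosity at QTL")
      }
      d <- d * sqrt(sigma2_D / vd)
    } else {
      d <- d * 0
    }
    gv <- drop(W %*% a + H %*% d)
    truth <- list(
      qtl = qtl, qtl_id = colnames(G$calls)[qtl],
      add_effects = a, dom_effects = d, mu = mu,
      gv = setNames(mu + gv, individuals(G)),
      realized = list(sigma2_A = stats::var(drop(W %*% a)),
                      sigma2_D = stats::var(drop(H %*% d)))
    )
    class(truth) <- "SimTruth"
    truth
  })
}

#' True genetic values of arbitrary genotypes under a simulated architecture
#' @param truth a `SimTruth`
#' @param G a [genotype_matrix()] sharing the reference marker set
#' @return named numeric vector (includes `mu`)
#' @export
genetic_values <- function(truth, G) {
  W <- G$calls[, truth$qtl, drop = FALSE]
  H <- (W == 0L) * 1
  setNames(truth$mu + drop(W %*% truth$add_effects + H %*% truth$dom_effects),
           individuals(G))
}

#' Simulate phenotypes from a trait architecture
#'
#' `phenotype = mu + genetic value + N(0, sigma2_e)`, optionally plus an
#' environment-specific genotype-by-environment term: per environment,
#' independent random marker effects are drawn (seeded by `env$id`) and
#' scaled so their variance in `G` equals `env$sigma2`.  Because the G-by-E
#' effects are genetic within an environment but uncorrelated across
#' environments, they inflate within-environment heritability while eroding
#' across-environment (across-population) prediction — the year-effect
#' failure mode seen for unstable traits.
#'
#' @param truth a `SimTruth`
#' @param G genotypes of the individuals to phenotype
#' @param sigma2_e residual variance
#' @param seed integer seed for the residual draw
#' @param env optional list `list(id = <integer>, sigma2 = <variance>)`
#' @return named numeric phenotype vector
#' @export
simulate_phenotypes <- function(truth, G, sigma2_e, seed = 1L, env = NULL) {
  gv <- genetic_values(truth, G)
  n <- length(gv)
  y <- gv + with_seed(seed, stats::rnorm(n, 0, sqrt(sigma2_e)))
  if (!is.null(env) && env$sigma2 > 0) {
    b <- with_seed(sub_seed(9973L, env$id), stats::rnorm(ncol(G$calls)))
    ge <- drop(G$calls %*% b)
    vge <- stats::var(ge)
    if (vge > 0) y <- y + ge * sqrt(env$sigma2 / vge)
  }
  setNames(y, individuals(G))
}

#' Leaf area index from leaf dimensions
#'
#' Ellipse approximation: `length_cm * width_cm * 3.14`.
#'
#' @param length_cm,width_cm leaf length and width in cm (positive)
#' @return leaf area in cm^2
#' @export
leaf_area_index <- function(length_cm, width_cm) {
  stopifnot(all(length_cm > 0), all(width_cm > 0))
  length_cm * width_cm * 3.14
}

#' Pericarp color index from colorimeter readings
#'
#' `L* x b* / a*` from lightness `L*` and hue components `a*`, `b*`.
#'
#' @param L,a,b colorimeter values; `a` must be nonzero
#' @return color index
#' @export
pericarp_color_index <- function(L, a, b) {
  if (any(a == 0)) stop("a* = 0: color index undefined")
  L * b / a
}
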