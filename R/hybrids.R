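#' Expected F1 genotype at one locus
#'
#' Deterministic expectation coding for the F1 of two parents at a biallelic
#' locus: opposite homozygotes give a heterozygote, identical homozygotes are
#' transmitted unchanged, and any cross involving a heterozygous parent is
#' coded heterozygous (the most probable class, not a sampled gamete).
#' Symmetric in its arguments.
#'
#' @param g1,g2 parental calls in \{-1, 0, 1\} (vectorized)
#' @return F1 calls in \{-1, 0, 1\}
#' @export
infer_f1_genotype <- function(g1, g2) {
  if (anyNA(g1) || anyNA(g2)) {
    stop("missing parental call: impute parents before synthesizing hybrids")
  }
  stopifnot(all(g1 %in% c(-1L, 0L, 1L)), all(g2 %in% c(-1L, 0L, 1L)))
  out <- integer(length(g1))              # heterozygous unless parents agree
  same_hom <- g1 == g2 & g1 != 0L
  out[same_hom] <- g1[same_hom]
  out
}

#' All unordered parent pairs
#'
#' Enumerates the n(n-1)/2 unordered parental combinations in lexicographic
#' order; seed- vs pollen-parent roles are not distinguished.
#'
#' @param ids character vector of >= 2 distinct parent IDs
#' @return a crossing plan: data.frame with columns `parent1`, `parent2`
#'   (parent1 < parent2 lexicographically)
#' @export
all_pairs <- function(ids) {
  if (anyDuplicated(ids)) stop("duplicate parent IDs")
  if (length(ids) < 2) stop("need at least 2 parent IDs")
  ids <- sort(ids)
  idx <- utils::combn(length(ids), 2)
  plan <- data.frame(parent1 = ids[idx[1, ]], parent2 = ids[idx[2, ]],
                     stringsAsFactors = FALSE)
  plan[order(plan$parent1, plan$parent2), , drop = FALSE]
}

#' Randomly sample a crossing plan
#'
#' Draws `k` distinct unordered pairs uniformly without replacement from the
#' full candidate-cross space.
#'
#' @param ids parent IDs
#' @param k number of crosses to sample
#' @param seed integer seed for reproducibility
#' @return a crossing plan data.frame (see [all_pairs()])
#' @export
sample_plan <- function(ids, k, seed = 1L) {
  full <- all_pairs(ids)
  if (k > nrow(full)) {
    stop("k = ", k, " exceeds the ", nrow(full), " possible pairs")
  }
  pick <- with_seed(seed, sample.int(nrow(full), k))
  out <- full[sort(pick), , drop = FALSE]
  rownames(out) <- NULL
  out
}

canonical_pair <- function(p1, p2) {
  swap <- p1 > p2
  tmp <- p1[swap]; p1[swap] <- p2[swap]; p2[swap] <- tmp
  list(parent1 = p1, parent2 = p2)
}

hybrid_id <- function(p1, p2) {
  cp <- canonical_pair(p1, p2)
  paste0(cp$parent1, "x", cp$parent2)
}

validate_plan <- function(plan, ids) {
  stopifnot(all(c("parent1", "parent2") %in% names(plan)))
  if (any(plan$parent1 == plan$parent2)) stop("self-crosses are not allowed")
  unknown <- setdiff(c(plan$parent1, plan$parent2), ids)
  if (length(unknown)) {
    stop("unknown parent ID(s): ", paste(unknown, collapse = ", "))
  }
  if (anyDuplicated(hybrid_id(plan$parent1, plan$parent2))) {
    stop("duplicate unordered parent pairs in plan")
  }
  invisible(plan)
}

#' Synthesize expected F1 hybrid genotypes
#'
#' Applies [infer_f1_genotype()] locus-wise for every cross in the plan.
#' Hybrid IDs are canonicalized as `"P1xP2"` with lexicographically ordered
#' parent names so that reciprocal crosses collide by construction.
#'
#' @param G_parents fully imputed parental [genotype_matrix()]
#' @param plan crossing plan data.frame with columns `parent1`, `parent2`
#' @return a [genotype_matrix()] with one row per cross, markers identical to
#'   the parental matrix
#' @export
synthesize_hybrids <- function(G_parents, plan) {
  if (anyNA(G_parents$calls)) {
    stop("parental genotypes contain missing calls: impute first")
  }
  validate_plan(plan, individuals(G_parents))
  g1 <- G_parents$calls[plan$parent1, , drop = FALSE]
  g2 <- G_parents$calls[plan$parent2, , drop = FALSE]
  f1 <- matrix(0L, nrow(g1), ncol(g1))        # het unless same homozygote
  same_hom <- g1 == g2 & g1 != 0L
  f1[same_hom] <- g1[same_hom]
  rownames(f1) <- hybrid_id(plan$parent1, plan$parent2)
  colnames(f1) <- colnames(G_parents$calls)
  genotype_matrix(f1, G_parents$markers)
}
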