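#' Predict every candidate hybrid for each trait
#'
#' Synthesizes the expected F1 genotype of every cross in the plan and scores
#' it with each trait's fitted model.  Deterministic given the fits.
#'
#' @param fits named list of `gs_fit` objects, one per trait (names become the
#'   prediction columns)
#' @param G_parents fully imputed parental [genotype_matrix()]
#' @param plan crossing plan (see [all_pairs()], [sample_plan()])
#' @return data.frame with columns `hybrid`, `parent1`, `parent2`, and one
#'   prediction column per trait
#' @export
predict_all_hybrids <- function(fits, G_parents, plan) {
  stopifnot(is.list(fits), !is.null(names(fits)))
  Gh <- synthesize_hybrids(G_parents, plan)
  cp <- canonical_pair(plan$parent1, plan$parent2)
  out <- data.frame(hybrid = individuals(Gh), parent1 = cp$parent1,
                    parent2 = cp$parent2, stringsAsFactors = FALSE)
  for (trait in names(fits)) {
    out[[trait]] <- as.numeric(predict_genetic_values(fits[[trait]], Gh))
  }
  out
}

#' Predict genetic values of arbitrary genotypes with any fitted model
#'
#' Dispatches on the `gs_fit` family.  For kinship models (GBLUP) the kinship
#' between new individuals and the training set is rebuilt from stored
#' training genotypes, so the fit must have been created through
#' [fit_and_predict()]-style wrappers or carry `G_train`; the simplest route
#' is [gs_train()] below.
#'
#' @param fit a `gs_fit` carrying its training genotypes (`G_train`)
#' @param G_new [genotype_matrix()] of individuals to predict
#' @return named numeric vector
#' @export
predict_genetic_values <- function(fit, G_new) {
  if (is.null(fit$G_train) && fit$family == "GBLUP") {
    stop("fit does not carry training genotypes; use gs_train()")
  }
  switch(fit$family,
    GBLUP = {
      G_train <- fit$G_train
      keep <- setdiff(individuals(G_new), individuals(G_train))
      calls <- rbind(G_train$calls, G_new$calls[keep, , drop = FALSE])
      G <- genotype_matrix(calls, G_train$markers)
      freq <- marker_allele_freq(G_train[names(fit$y), ])
      poly <- freq > 0 & freq < 1
      Gp <- G[, poly]
      A <- additive_kinship(Gp, freq = freq[poly])
      D <- if (!is.null(fit$vc$sigma2_D)) {
        dominance_kinship(Gp, freq = freq[poly])
      } else NULL
      predict_gblup(fit, A, D_full = D,
                    test_ids = individuals(G_new))
    },
    RKHS = predict_rkhs(fit, G_new),
    TreeEnsemble = predict_forest(fit, G_new$calls),
    # marker-effect families
    predict_markers(fit, G_new$calls,
                    if (is.null(fit$beta_het)) NULL else
                      heterozygosity_design(G_new, center = FALSE))
  )
}

#' Train a model for hybrid scoring
#'
#' Thin wrapper over [fit_and_predict()]'s fitting path that attaches the
#' training genotypes to the returned `gs_fit`, so the fit can later score
#' synthesized hybrids via [predict_genetic_values()].  The training set may
#' pool populations (e.g. inbred parents plus test F1s).
#'
#' @param y named phenotype vector
#' @param G fully imputed [genotype_matrix()] covering the phenotyped IDs
#' @param model a [gs_model()] spec
#' @return a `gs_fit` carrying `G_train`
#' @export
gs_train <- function(y, G, model) {
  fp <- fit_and_predict(model, G, y, test_ids = names(y)[1])
  fit <- fp$fit
  fit$G_train <- G[names(y), ]
  fit
}

#' Define a selection class
#'
#' @param name class label
#' @param trait prediction column the class selects on
#' @param type `"high"` (above `quantile`), `"low"` (below `1 - quantile`),
#'   or `"intermediate"` (inside the `band` quantile band of `trait`; when
#'   `trait2` is given the band applies to both traits)
#' @param quantile outer-quantile threshold for high/low classes (default 0.9)
#' @param band two quantiles bounding the intermediate band (default
#'   `c(0.4, 0.6)`)
#' @param trait2 optional second trait for intermediate classes
#' @return a `selection_class` list
#' @export
selection_class <- function(name, trait, type = c("high", "low", "intermediate"),
                            quantile = 0.9, band = c(0.4, 0.6), trait2 = NULL) {
  type <- match.arg(type)
  stopifnot(quantile > 0, quantile < 1, all(band > 0), all(band < 1))
  structure(list(name = name, trait = trait, type = type, quantile = quantile,
                 band = band, trait2 = trait2), class = "selection_class")
}

#' Select parental combinations into phenotype classes
#'
#' Ranks candidate hybrids by their predicted values and draws each class in
#' turn from beyond its quantile threshold (high/low) or from inside its
#' quantile band (intermediate).  Already-selected hybrids and excluded
#' parent pairs (e.g. crosses impossible due to flowering-time gaps) are
#' skipped; ties are broken by hybrid ID order.  Classes are therefore
#' disjoint by construction.
#'
#' @param predictions output of [predict_all_hybrids()]
#' @param classes list of [selection_class()] definitions (applied in order)
#' @param n_per_class quota per class (single number or vector named by class)
#' @param exclude optional data.frame of parent pairs (`parent1`, `parent2`)
#'   that must never be selected
#' @return `predictions` rows for the selected hybrids with a `class` column
#' @export
select_classes <- function(predictions, classes, n_per_class = 5,
                           exclude = NULL) {
  stopifnot(is.list(classes))
  quota <- if (length(n_per_class) == 1) {
    setNames(rep(n_per_class, length(classes)),
             vapply(classes, `[[`, "", "name"))
  } else n_per_class
  excluded_ids <- character(0)
  if (!is.null(exclude) && nrow(exclude)) {
    excluded_ids <- hybrid_id(exclude$parent1, exclude$parent2)
  }
  pred <- predictions[order(predictions$hybrid), , drop = FALSE]
  taken <- character(0)
  out <- list()
  for (cl in classes) {
    stopifnot(inherits(cl, "selection_class"))
    v <- pred[[cl$trait]]
    if (is.null(v)) stop("no prediction column '", cl$trait, "'")
    eligible <- !(pred$hybrid %in% c(taken, excluded_ids))
    if (cl$type == "high") {
      thr <- stats::quantile(v, cl$quantile)
      pool <- which(eligible & v >= thr)
      pool <- pool[order(-v[pool], pred$hybrid[pool])]
    } else if (cl$type == "low") {
      thr <- stats::quantile(v, 1 - cl$quantile)
      pool <- which(eligible & v <= thr)
      pool <- pool[order(v[pool], pred$hybrid[pool])]
    } else {
      lo <- stats::quantile(v, cl$band[1]); hi <- stats::quantile(v, cl$band[2])
      inband <- v >= lo & v <= hi
      if (!is.null(cl$trait2)) {
        v2 <- pred[[cl$trait2]]
        lo2 <- stats::quantile(v2, cl$band[1]); hi2 <- stats::quantile(v2, cl$band[2])
        inband <- inband & v2 >= lo2 & v2 <= hi2
      }
      pool <- which(eligible & inband)
      ctr <- stats::median(v)
      pool <- pool[order(abs(v[pool] - ctr), pred$hybrid[pool])]
    }
    q <- quota[[cl$name]]
    if (length(pool) < q) {
      stop("class '", cl$name, "': only ", length(pool),
           " eligible hybrids for a quota of ", q)
    }
    sel <- pred[pool[seq_len(q)], , drop = FALSE]
    sel$class <- cl$name
    taken <- c(taken, sel$hybrid)
    out[[cl$name]] <- sel
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Correlate predicted and observed values over developed hybrids
#'
#' Per-trait Pearson correlation over the selected-and-phenotyped set.  Note
#' the caveat: when selection acted on a trait, the selected set spans the
#' extremes of that trait, which inflates its correlation relative to the
#' unselected cross-validation accuracy.
#'
#' @param predicted data.frame with `hybrid` plus trait prediction columns
#'   (e.g. [predict_all_hybrids()] rows for the developed hybrids)
#' @param observed data.frame with `hybrid` plus observed trait columns
#' @param traits trait columns to correlate (default: all shared non-ID columns)
#' @return data.frame with columns `trait` and `r`
#' @export
evaluate_selection <- function(predicted, observed, traits = NULL) {
  if (is.null(traits)) {
    traits <- setdiff(intersect(names(predicted), names(observed)),
                      c("hybrid", "parent1", "parent2", "class"))
  }
  ids <- intersect(predicted$hybrid, observed$hybrid)
  if (length(ids) < 3) stop("need at least 3 hybrids with both values")
  data.frame(
    trait = traits,
    r = vapply(traits, function(tr) {
      pearson_accuracy(setNames(predicted[[tr]], predicted$hybrid)[ids],
                       setNames(observed[[tr]], observed$hybrid)[ids])
    }, numeric(1)),
    row.names = NULL
  )
}
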