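#' Narrow-sense (additive) heritability
#'
#' `h2_A = sigma2_A / (sigma2_A + sigma2_e)`.
#'
#' @param vc list with elements `sigma2_A` and `sigma2_e` (as in a
#'   [fit_gblup()] `$vc`)
#' @return heritability in \[0, 1\]
#' @export
h2_additive <- function(vc) {
  s2A <- vc$sigma2_A
  s2e <- vc$sigma2_e
  stopifnot(s2A >= 0, s2e >= 0)
  if (s2A + s2e == 0) stop("both variance components are zero: h2 undefined")
  s2A / (s2A + s2e)
}

#' Additive-plus-dominance heritability
#'
#' `h2_AD = (sigma2_A + sigma2_D) / (sigma2_A + sigma2_D + sigma2_e)`.
#'
#' @param vc list with elements `sigma2_A`, `sigma2_D` and `sigma2_e`
#' @return heritability in \[0, 1\]
#' @export
h2_additive_dominant <- function(vc) {
  if (is.null(vc$sigma2_D)) {
    stop("sigma2_D absent: fit the additive-plus-dominance model first")
  }
  s2G <- vc$sigma2_A + vc$sigma2_D
  s2e <- vc$sigma2_e
  stopifnot(s2G >= 0, s2e >= 0)
  if (s2G + s2e == 0) stop("all variance components are zero: h2 undefined")
  s2G / (s2G + s2e)
}

#' Estimate heritability for one trait
#'
#' Fits the additive (and, for `effects = "AD"`, the joint additive +
#' dominance) kinship model and returns heritability.  Under the Gibbs
#' engine, h2 is computed per posterior draw and summarized by its posterior
#' mean, rather than as a ratio of posterior-mean components.
#'
#' Separate sigma2_A and sigma2_D from a joint fit should be read with
#' caution: A and D built from the same markers are correlated, so the split
#' between them is poorly identified even when their sum (and hence h2_AD) is
#' stable.  On near-fully-homozygous inbred panels the dominance term can
#' absorb noise and inflate h2_AD (accidental overfitting); estimate h2_AD on
#' populations with real heterozygosity, such as F1s.
#'
#' @param y named phenotype vector
#' @param A additive kinship; `D` dominance kinship (required for `"AD"`)
#' @param effects `"A"` or `"AD"`
#' @param engine,... passed to [fit_gblup()]
#' @return list with `h2`, `vc`, `fit`, `effects`, `engine`
#' @export
estimate_heritability <- function(y, A, D = NULL, effects = c("A", "AD"),
                                  engine = "REML", ...) {
  effects <- match.arg(effects)
  if (effects == "AD" && is.null(D)) stop("effects = 'AD' requires D")
  fit <- fit_gblup(y, A, D = if (effects == "AD") D else NULL,
                   engine = engine, ...)
  h2 <- if (!is.null(fit$vc_draws)) {
    draws <- fit$vc_draws
    gcols <- seq_len(ncol(draws) - 1)
    mean(rowSums(draws[, gcols, drop = FALSE]) / rowSums(draws))
  } else if (effects == "A") {
    h2_additive(fit$vc)
  } else {
    h2_additive_dominant(fit$vc)
  }
  list(h2 = h2, vc = fit$vc, fit = fit, effects = effects, engine = engine)
}
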