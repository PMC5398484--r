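# Variance decomposition of regional genetic effects into persistent,
# rescaling and heterogeneity fractions; BLUP cis-genetic prediction;
# enrichment statistics for opposite-effect annotation.

#' Decompose regional genetic variance by architecture
#'
#' Fits the block, rank-one and full trait-context covariance models and
#' attributes explained set variance incrementally along the nested
#' hierarchy: the block model's explained variance is the persistent
#' fraction; the increment from block to rank-one is the rescaling-GxC
#' fraction; the increment from rank-one to full is the heterogeneity-GxC
#' fraction (increments floored at zero so fractions stay interpretable).
#' Explained variance under kind k is the mean over contexts of
#' \eqn{\hat C_s^{(k)}[c,c]} (the diagonal of Rs is normalized to mean 1 by
#' region standardization) divided by the per-context trait variance.
#'
#' @inheritParams testRegion
#' @return list with fractions (persistent, rescaling, heterogeneity,
#'   totalSet, residual), the per-kind explained variances, and convergence
#'   flags.
#' @export
decomposeVariance <- function(design, region, options = list()) {
  pre <- .regionPrecompute(design, region)
  if (design@layout == "complete") {
    vtot <- apply(design@Y, 2, stats::var)
  } else {
    vtot <- vapply(split(design@y, design@context), stats::var, 0)
  }
  kinds <- c("block", "rank1", "full")
  fits <- lapply(setNames(kinds, kinds), function(k) .fitFromPre(pre, k, options))
  expl <- vapply(fits, function(f) mean(diag(f@Cs) / vtot), 0)
  persistent <- expl["block"]
  rescaling <- max(0, expl["rank1"] - expl["block"])
  heterogeneity <- max(0, expl["full"] - expl["rank1"])
  totalSet <- persistent + rescaling + heterogeneity
  list(fractions = c(persistent = unname(persistent),
                     rescaling = unname(rescaling),
                     heterogeneity = unname(heterogeneity),
                     totalSet = unname(totalSet),
                     residual = unname(max(0, 1 - totalSet))),
       explained = expl,
       converged = vapply(fits, function(f) f@converged, TRUE),
       fits = fits)
}

#' Best linear unbiased predictor of cis genetic values
#'
#' Computes y_cis = sigma2_cis * K_cis * V^{-1} * (y - mu) for a fitted
#' single-context model with total covariance V.
#'
#' @param y trait vector for one context.
#' @param Kcis cis realized relatedness matrix.
#' @param sigma2cis estimated variance explained by cis variants.
#' @param V total estimated covariance matrix (positive definite).
#' @param mu estimated mean (scalar or vector).
#' @return vector of predicted cis genetic values.
#' @export
blupCis <- function(y, Kcis, sigma2cis, V, mu = 0) {
  ch <- tryCatch(chol(V), error = function(e) stop("V is singular or not positive definite"))
  r <- y - mu
  as.numeric(sigma2cis * (Kcis %*% backsolve(ch, forwardsolve(t(ch), r))))
}

#' Fit a single-context set model (for BLUP)
#'
#' Univariate REML fit of y = F b + u + e with u ~ N(0, sigma2_cis Rs),
#' e ~ N(0, sigma2_n I), via the same machinery as the multi-context model
#' (C = 1, block kind).
#'
#' @param y trait vector.
#' @param region a \linkS4class{RegionGenotypes}.
#' @param F fixed-effect covariates (default intercept).
#' @param options optimizer options.
#' @return list with sigma2cis, sigma2n, mu (fitted fixed effects), V (total
#'   covariance), and the blup predictions for y.
#' @export
fitSingleContext <- function(y, region, F = matrix(1, length(y), 1),
                             options = list()) {
  des <- completeDesign(matrix(y, ncol = 1), F)
  fit <- fitModel(des, region, "block", options)
  s2c <- fit@Cs[1, 1]
  s2n <- fit@Cn[1, 1]
  V <- s2c * region@Rs + diag(s2n, length(y))
  mu <- as.numeric(F %*% fit@B)
  list(sigma2cis = s2c, sigma2n = s2n, mu = mu, V = V,
       blup = blupCis(y, region@Rs, s2c, V, mu), fit = fit)
}

#' Odds ratio and one-sided exact enrichment p-value for a 2x2 table
#'
#' Sample odds ratio (a*d)/(b*c) and the one-sided (enrichment)
#' hypergeometric p-value of Fisher's exact test.
#'
#' @param table 2x2 matrix of non-negative integer counts
#'   rbind(c(a, b), c(c, d)).
#' @return list with oddsRatio, pValue and an \code{infinite} flag set when
#'   a zero cell makes the sample odds ratio infinite.
#' @export
enrichmentOddsRatio <- function(table) {
  tab <- as.matrix(table)
  stopifnot(all(dim(tab) == c(2, 2)), all(tab >= 0), all(tab == round(tab)))
  denom <- tab[1, 2] * tab[2, 1]
  orHat <- if (denom == 0) Inf else (tab[1, 1] * tab[2, 2]) / denom
  p <- stats::fisher.test(tab, alternative = "greater")$p.value
  list(oddsRatio = orHat, pValue = p, infinite = !is.finite(orHat))
}
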