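# Phenotype and genotype preparation: rank-based inverse-normal
# transformation, covariate regression, genotype principal components and
# region standardization.

#' Quantile-normalize a trait vector to a standard normal
#'
#' Ranks are mapped to Gaussian quantiles at (rank - offset) / n.  Ties are
#' resolved with averaged ranks so that integer-valued traits normalize
#' deterministically.  Applied per context in multi-context analyses.
#'
#' @param values numeric trait vector (length >= 3, non-constant).
#' @param offset rank offset; default 0.5 gives the (rank - 0.5)/n grid.
#' @return normalized vector with (approximately) zero mean and unit variance.
#' @export
quantileNormalize <- function(values, offset = 0.5) {
  if (length(values) < 3) stop("need at least 3 values to quantile-normalize")
  if (stats::sd(values) < 1e-300) stop("cannot quantile-normalize a constant vector")
  r <- rank(values, ties.method = "average")
  qnorm((r - offset) / length(values))
}

#' Principal components of the realized relatedness matrix
#'
#' Computes eigenvectors of the standardized genome-wide realized relatedness
#' matrix G G' / S, for inclusion as fixed-effect covariates to adjust for
#' population structure.  The sign of each component is fixed so that the
#' loading with the largest magnitude is positive, making the output
#' deterministic across runs and platforms.
#'
#' @param genomewide a \linkS4class{DosageMatrix} (or plain dosage matrix).
#' @param nComponents number of components (default 10).
#' @return N x nComponents matrix of unit-norm, mutually orthogonal PCs.
#' @export
computePCs <- function(genomewide, nComponents = 10) {
  d <- if (is(genomewide, "DosageMatrix")) genomewide@dosages else as.matrix(genomewide)
  if (nComponents >= nrow(d)) stop("nComponents must be smaller than the number of individuals")
  G <- .standardizeDosages(d)
  K <- tcrossprod(G) / ncol(G)
  ev <- eigen(K, symmetric = TRUE)
  V <- ev$vectors[, seq_len(nComponents), drop = FALSE]
  for (j in seq_len(ncol(V))) {
    i <- which.max(abs(V[, j]))
    if (V[i, j] < 0) V[, j] <- -V[, j]
  }
  colnames(V) <- paste0("PC", seq_len(ncol(V)))
  V
}

#' Regress fixed-effect covariates out of a trait
#'
#' Ordinary-least-squares residuals of y on the covariate columns; residuals
#' are exactly orthogonal to every covariate column.
#'
#' @param y numeric trait vector.
#' @param covariates full-column-rank covariate matrix.
#' @return residual trait vector.
#' @export
regressOutCovariates <- function(y, covariates) {
  X <- as.matrix(covariates)
  qx <- qr(X)
  if (qx$rank < ncol(X)) stop("covariate matrix is rank deficient")
  as.numeric(qr.resid(qx, y))
}

# mean-impute missing entries and standardize columns (population scaling,
# so that sum_i G[i,v]^2 = N exactly and mean(diag(G G'/S)) = 1)
.standardizeDosages <- function(d) {
  d <- as.matrix(d)
  if (anyNA(d)) {
    mu <- colMeans(d, na.rm = TRUE)
    idx <- which(is.na(d), arr.ind = TRUE)
    d[idx] <- mu[idx[, 2]]
  }
  ctr <- sweep(d, 2, colMeans(d))
  s <- sqrt(colMeans(ctr^2))
  keep <- s > 1e-12
  sweep(ctr[, keep, drop = FALSE], 2, s[keep], "/")
}

#' Standardize a region's dosages and derive the local relatedness matrix
#'
#' Applies the minor-allele-frequency filter, drops monomorphic variants,
#' scales each surviving variant to mean 0 / variance 1 and computes
#' Rs = G G' / S.  Missing dosages (from file input) are mean-imputed per
#' variant before standardization.
#'
#' @param raw a \linkS4class{DosageMatrix} or plain dosage matrix.
#' @param mafMin minimum allele frequency; variants with alternate-allele
#'   frequency outside [mafMin, 1 - mafMin] are dropped (default 0.02).
#' @return A \linkS4class{RegionGenotypes}.
#' @export
standardizeRegion <- function(raw, mafMin = 0.02) {
  if (is(raw, "DosageMatrix")) {
    d <- raw@dosages; pos <- raw@positions; chrom <- raw@chrom
  } else {
    d <- as.matrix(raw); pos <- seq_len(ncol(d)) - 1; chrom <- "1"
  }
  if (ncol(d) < 1) stop("degenerate region: no variants")
  if (anyNA(d)) {
    mu <- colMeans(d, na.rm = TRUE)
    idx <- which(is.na(d), arr.ind = TRUE)
    d[idx] <- mu[idx[, 2]]
  }
  f <- colMeans(d) / 2
  keep <- f >= mafMin & f <= 1 - mafMin & apply(d, 2, stats::sd) > 1e-12
  if (sum(keep) < 1) stop("degenerate region: no variants survive the MAF filter")
  d <- d[, keep, drop = FALSE]
  pos <- pos[keep]
  ctr <- sweep(d, 2, colMeans(d))
  G <- sweep(ctr, 2, sqrt(colMeans(ctr^2)), "/")
  S <- ncol(G)
  ids <- paste0(chrom, ":", format(pos, scientific = FALSE, trim = TRUE))
  new("RegionGenotypes", G = G, S = as.integer(S), Rs = tcrossprod(G) / S,
      ids = ids, positions = as.numeric(pos), chrom = chrom)
}

#' Assemble a fixed-effect covariate matrix
#'
#' Binds an intercept, measured covariates and principal components into a
#' single full-rank matrix with provenance labels.
#'
#' @param n number of individuals.
#' @param measured optional matrix of measured covariates.
#' @param pcs optional matrix of principal components.
#' @return N x K covariate matrix with a "provenance" attribute.
#' @export
buildCovariates <- function(n, measured = NULL, pcs = NULL) {
  parts <- list(intercept = matrix(1, n, 1))
  if (!is.null(measured)) parts$measured <- as.matrix(measured)
  if (!is.null(pcs)) parts$pc <- as.matrix(pcs)
  F <- do.call(cbind, parts)
  prov <- rep(names(parts), vapply(parts, ncol, 1L))
  if (qr(F)$rank < ncol(F)) stop("covariate matrix is rank deficient")
  colnames(F) <- make.unique(c("intercept",
                               if (!is.null(measured)) colnames(as.matrix(measured)) %||% paste0("X", seq_len(ncol(as.matrix(measured)))),
                               if (!is.null(pcs)) colnames(as.matrix(pcs)) %||% paste0("PC", seq_len(ncol(as.matrix(pcs))))))
  attr(F, "provenance") <- prov
  F
}
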