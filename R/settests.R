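# The three set tests (mtSet, iSet, iSet-het), null LLR generation by
# permutation / parametric bootstrap, pooled empirical p-values, and the
# single-variant interaction baseline with multiple-testing helpers.

.testDefs <- list(mtSet = "null", iSet = "block", iSetHet = "rank1")

# Likelihood-ratio differences below the optimizer's resolution are ties:
# they are clipped to exactly zero, which preserves the boundary mass that
# arises because the trait-context covariances are constrained to be PSD.
.clipLLR <- function(x) if (!is.finite(x) || x < 1e-6) 0 else x

#' Run the three interaction set tests on one region
#'
#' Fits the four covariance-structure models (null, block, rank1, full) and
#' returns the clipped likelihood-ratio statistics
#' LLR = max(0, 2 * (logLik(full) - logLik(reduced))): mtSet (full vs null),
#' iSet (full vs block) and iSet-het (full vs rank1).  Statistics can sit
#' exactly at zero because the trait-context covariances are constrained to
#' be positive semidefinite (boundary of the parameter space).
#'
#' @param design a \linkS4class{StudyDesign}.
#' @param region a \linkS4class{RegionGenotypes}.
#' @param regionId identifier stored with the result.
#' @param options fitting options passed to the optimizer (see
#'   \code{\link{fitModel}}).
#' @return A \linkS4class{RegionTestResult}.
#' @export
testRegion <- function(design, region, regionId = "region", options = list()) {
  pre <- .regionPrecompute(design, region)
  .testFromPre(pre, regionId, options)
}

.testFromPre <- function(pre, regionId = "region", options = list()) {
  fits <- lapply(setNames(covKinds, covKinds), function(k)
    .fitFromPre(pre, k, options))
  llFull <- fits$full@logLik
  llr <- c(mtSet = .clipLLR(2 * (llFull - fits$null@logLik)),
           iSet = .clipLLR(2 * (llFull - fits$block@logLik)),
           iSetHet = .clipLLR(2 * (llFull - fits$rank1@logLik)))
  new("RegionTestResult", regionId = regionId, fits = fits, llr = llr,
      converged = vapply(fits, function(f) f@converged, TRUE))
}

#' Draw null LLR replicates for the three tests
#'
#' mtSet nulls come from permuting the individual ordering of the region
#' genotypes relative to the phenotypes (the trait-context covariance of Y
#' is untouched); iSet nulls are parametric bootstraps from the fitted block
#' (persistent) model; iSet-het nulls are parametric bootstraps from the
#' fitted rank-one (rescaling) model.  In each case the full model and the
#' respective reduced model are refitted on the replicate.  Non-converged
#' replicate fits are redrawn (up to 3 attempts) with a perturbed seed.
#'
#' @inheritParams testRegion
#' @param J replicates per test.
#' @param seed base seed; replicate j of test t uses a derived child stream.
#' @param tests subset of c("mtSet", "iSet", "iSetHet").
#' @return named list of length-J numeric LLR vectors, with a
#'   \code{provenance} attribute (data.frame of test, replicate, seed).
#' @export
drawNullLLRs <- function(design, region, J = 30L, seed = 1L,
                         tests = c("mtSet", "iSet", "iSetHet"),
                         options = list()) {
  pre <- .regionPrecompute(design, region)
  .nullsFromPre(pre, J, seed, tests, options)
}

.nullsFromPre <- function(pre, J, seed, tests = c("mtSet", "iSet", "iSetHet"),
                          options = list()) {
  tests <- match.arg(tests, several.ok = TRUE)
  out <- list()
  prov <- list()
  nullFits <- list()
  for (tname in tests) {
    reducedKind <- .testDefs[[tname]]
    llrs <- numeric(J)
    seeds <- integer(J)
    if (tname != "mtSet" && is.null(nullFits[[reducedKind]]))
      nullFits[[reducedKind]] <- .fitFromPre(pre, reducedKind, options)
    for (j in seq_len(J)) {
      for (attempt in 1:3) {
        sj <- childSeed(seed, match(tname, names(.testDefs)), j, attempt)
        if (tname == "mtSet") {
          perm <- withSeed(sj, sample.int(pre$N))
          preJ <- .preWithPermutedG(pre, perm)
        } else {
          Ystar <- .sampleFromFit(pre, nullFits[[reducedKind]], sj)
          preJ <- .preWithY(pre, Ystar)
        }
        fFull <- .fitFromPre(preJ, "full", options)
        fRed <- if (tname == "mtSet") .fitFromPre(preJ, "null", options)
                else .fitFromPre(preJ, reducedKind, options)
        if (fFull@converged && fRed@converged) break
      }
      llrs[j] <- .clipLLR(2 * (fFull@logLik - fRed@logLik))
      seeds[j] <- sj
    }
    out[[tname]] <- llrs
    prov[[tname]] <- data.frame(test = tname, replicate = seq_len(J),
                                seed = seeds)
  }
  attr(out, "provenance") <- do.call(rbind, prov)
  out
}

#' Pool per-region null draws into a NullPool
#'
#' @param perRegion list (one element per region) of named null LLR lists as
#'   returned by \code{\link{drawNullLLRs}}.
#' @param regionIds region identifiers.
#' @return A \linkS4class{NullPool}.
#' @export
makeNullPool <- function(perRegion, regionIds = NULL) {
  stopifnot(length(perRegion) >= 1)
  tests <- names(perRegion[[1]])
  J <- length(perRegion[[1]][[1]])
  Tn <- length(perRegion)
  ids <- regionIds %||% as.character(seq_len(Tn))
  llr <- lapply(setNames(tests, tests), function(t)
    unlist(lapply(perRegion, `[[`, t), use.names = FALSE))
  prov <- do.call(rbind, lapply(seq_along(perRegion), function(i) {
    p <- attr(perRegion[[i]], "provenance")
    if (is.null(p)) return(NULL)
    p$region <- ids[i]
    p
  }))
  new("NullPool", llr = llr, J = as.integer(J), T = as.integer(Tn),
      provenance = prov %||% data.frame())
}

#' Empirical p-values from pooled null LLRs
#'
#' p = (1 + #\{null >= observed\}) / (1 + J*T), with ties counted as
#' exceedances; the +1 smoothing keeps p strictly positive while preserving
#' the resolution floor of roughly 1/(J*T).  Benjamini-Hochberg q-values are
#' computed per test across regions.
#'
#' @param results list of \linkS4class{RegionTestResult}.
#' @param nulls a \linkS4class{NullPool} covering the same tests.
#' @return data.frame with region id and, per test, the observed LLR,
#'   empirical p-value and BH q-value.
#' @export
poolAndPValues <- function(results, nulls) {
  stopifnot(is(nulls, "NullPool"), length(results) >= 1)
  tests <- names(nulls@llr)
  if (any(vapply(nulls@llr, length, 1L) == 0)) stop("empty null pool")
  df <- data.frame(region = vapply(results, function(r) r@regionId, ""))
  for (t in tests) {
    pool <- nulls@llr[[t]]
    obs <- vapply(results, function(r) unname(r@llr[t]), 0)
    p <- vapply(obs, function(o) (1 + sum(pool >= o)) / (1 + length(pool)), 0)
    df[[paste0("llr_", t)]] <- obs
    df[[paste0("p_", t)]] <- p
    df[[paste0("q_", t)]] <- p.adjust(p, method = "BH")
  }
  df
}

# ---------------------------------------------------------------------------
# single-variant interaction baseline
# ---------------------------------------------------------------------------

#' Single-variant association and interaction scan (baseline)
#'
#' For every variant in the region, a fixed-effect model with the variant's
#' persistent effect and its variant-by-context interaction is tested with
#' the residual covariance Cn (x) I estimated once under the no-genetics
#' (null-kind) model; the interaction is a 1-degree-of-freedom Wald test
#' (C = 2).  The region-level p-value is the minimum interaction p-value
#' multiplied by the number of tests (Bonferroni) or by the effective test
#' count estimated from local LD.
#'
#' @inheritParams testRegion
#' @param adjust "bonferroni" or "effective".
#' @param effFraction variance fraction for \code{\link{effectiveTests}}.
#' @return list with per-variant data.frame (assocP, interP), the region
#'   p-value, the adjustment used and the index of the lead variant.
#' @export
singleVariantInteractionScan <- function(design, region,
                                         adjust = c("bonferroni", "effective"),
                                         effFraction = 0.995,
                                         options = list()) {
  adjust <- match.arg(adjust)
  stopifnot(design@nContexts == 2L)
  nullFit <- fitModel(design, region, "null", options)
  G <- region@G
  S <- region@S
  N <- designN(design)
  if (design@layout == "complete") {
    Ln <- t(chol(nullFit@Cn))
    Wh <- t(solve(Ln))                      # C x C whitener (right-multiply)
    Yw <- design@Y %*% Wh
    yv <- as.vector(Yw)
    F <- design@F
    # covariate design in whitened vec space: column block for context a is
    # Wh[a, i] * F stacked over whitened contexts i
    K <- ncol(F)
    X0 <- matrix(0, 2 * N, 2 * K)
    for (a in 1:2) for (i in 1:2)
      X0[(i - 1) * N + seq_len(N), (a - 1) * K + seq_len(K)] <-
        Wh[a, i] * F
    cPers <- c(1, 1)                        # persistent contrast over contexts
    cInt <- c(0, 1)                         # interaction: context-2 deviation
    wPers <- as.numeric(crossprod(Wh, cPers))
    wInt <- as.numeric(crossprod(Wh, cInt))
    q0 <- qr(X0)
    yr <- qr.resid(q0, yv)
    stats <- vapply(seq_len(S), function(v) {
      g <- G[, v]
      if (stats::sd(g) < 1e-12) return(c(NA_real_, NA_real_))
      Xg <- cbind(c(wPers[1] * g, wPers[2] * g), c(wInt[1] * g, wInt[2] * g))
      Xr <- qr.resid(q0, Xg)
      A <- crossprod(Xr)
      b <- crossprod(Xr, yr)
      bet <- solve(A, b)
      Vb <- solve(A)                        # unit residual variance (known Cn)
      zInt2 <- bet[2]^2 / Vb[2, 2]
      zAssoc2 <- as.numeric(crossprod(bet, A %*% bet))
      c(pchisq(zAssoc2, 2, lower.tail = FALSE),
        pchisq(zInt2, 1, lower.tail = FALSE))
    }, numeric(2))
  } else {
    ctx <- design@context
    w <- 1 / sqrt(diag(nullFit@Cn)[ctx])
    F <- design@F
    K <- ncol(F)
    X0 <- matrix(0, N, 2 * K)
    for (a in 1:2) {
      rows <- which(ctx == a)
      X0[rows, (a - 1) * K + seq_len(K)] <- F[rows, , drop = FALSE]
    }
    X0 <- X0 * w
    yv <- design@y * w
    q0 <- qr(X0)
    yr <- qr.resid(q0, yv)
    stats <- vapply(seq_len(S), function(v) {
      g <- G[, v]
      if (stats::sd(g) < 1e-12) return(c(NA_real_, NA_real_))
      Xg <- cbind(g, g * (ctx == 2L)) * w
      Xr <- qr.resid(q0, Xg)
      A <- crossprod(Xr)
      b <- crossprod(Xr, yr)
      bet <- solve(A, b)
      Vb <- solve(A)
      zInt2 <- bet[2]^2 / Vb[2, 2]
      zAssoc2 <- as.numeric(crossprod(bet, A %*% bet))
      c(pchisq(zAssoc2, 2, lower.tail = FALSE),
        pchisq(zInt2, 1, lower.tail = FALSE))
    }, numeric(2))
  }
  perVariant <- data.frame(id = region@ids, position = region@positions,
                           assocP = stats[1, ], interP = stats[2, ])
  skipped <- sum(is.na(perVariant$interP))
  nTests <- if (adjust == "bonferroni") S - skipped
            else effectiveTests(region, effFraction)
  minP <- min(perVariant$interP, na.rm = TRUE)
  list(perVariant = perVariant,
       regionP = min(1, nTests * minP),
       lead = which.min(perVariant$interP),
       adjust = adjust, nTests = nTests, skipped = skipped)
}

#' Effective number of independent tests from local LD
#'
#' Eigenvalue-based count from the variant correlation matrix: the smallest
#' k whose top-k eigenvalues capture a configured fraction of the total
#' variance.  Approximates published effective-test estimators without
#' claiming to reimplement any specific one.
#'
#' @param region a \linkS4class{RegionGenotypes}.
#' @param fraction variance fraction to capture (default 0.995).
#' @return integer in [1, S].
#' @export
effectiveTests <- function(region, fraction = 0.995) {
  G <- region@G
  S <- ncol(G)
  if (S == 1) return(1L)
  R <- stats::cor(G)
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  ev <- pmax(ev, 0)
  as.integer(min(S, which(cumsum(ev) / sum(ev) >= fraction)[1]))
}

#' Baseline heterogeneity score from per-context lead variants
#'
#' Returns 1 - r^2 between the per-context lead variants when both contexts
#' reach the significance threshold, and 0 otherwise.
#'
#' @param p1,p2 marginal association p-values of the lead variant in each
#'   context.
#' @param r2 squared correlation (LD) between the two lead variants.
#' @param threshold significance threshold on the per-context p-values.
#' @return score in [0, 1].
#' @export
heterogeneityBaselineScore <- function(p1, p2, r2, threshold = 0.01) {
  if (is.na(p1) || is.na(p2) || p1 > threshold || p2 > threshold) return(0)
  if (is.na(r2)) return(0)
  max(0, min(1, 1 - r2))
}

#' Classify a region's interaction architecture from single-variant results
#'
#' Rule-based labelling of per-context lead (and optional secondary)
#' variants: "distinct-leads" when both contexts are significant and the
#' leads are in low LD (r^2 < 0.2); "shared-lead" when the leads are in
#' high LD (r^2 > 0.8), sub-labelled by presence of a context-specific
#' secondary association and by effect-direction concordance;
#' "intermediate-LD" (0.2 <= r^2 <= 0.8) is unresolved.
#'
#' @param leadR2 LD r^2 between the per-context lead variants (NA allowed).
#' @param leadSignificant length-2 logical: marginal significance per context.
#' @param effectSigns length-2 numeric: sign of the lead-variant effect per
#'   context (used for shared leads).
#' @param secondarySignificant length-2 logical: significance of secondary
#'   associations per context.
#' @param secondaryR2 LD r^2 between secondary lead variants (NA allowed).
#' @return list with \code{class}, \code{direction} ("same", "opposite" or
#'   NA) and \code{secondary} ("context-specific-secondary", "none" or NA).
#' @export
classifyArchitecture <- function(leadR2, leadSignificant,
                                 effectSigns = c(NA_real_, NA_real_),
                                 secondarySignificant = c(FALSE, FALSE),
                                 secondaryR2 = NA_real_) {
  res <- list(class = "unresolved", direction = NA_character_,
              secondary = NA_character_)
  if (!all(leadSignificant)) return(res)
  if (is.na(leadR2)) return(res)
  if (leadR2 < 0.2) {
    res$class <- "distinct-leads"
  } else if (leadR2 > 0.8) {
    res$class <- "shared-lead"
    if (!anyNA(effectSigns))
      res$direction <- if (prod(sign(effectSigns)) < 0) "opposite" else "same"
    ctxSpecific <- xor(secondarySignificant[1], secondarySignificant[2]) ||
      (all(secondarySignificant) && !is.na(secondaryR2) && secondaryR2 < 0.2)
    res$secondary <- if (isTRUE(ctxSpecific)) "context-specific-secondary" else "none"
  } else {
    res$class <- "intermediate-LD"
  }
  res
}
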