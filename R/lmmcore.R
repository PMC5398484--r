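# Matrix-variate LMM core: efficient REML objective (C++ backend), dense
# likelihood oracle, constrained fitting, and sampling from fitted models.
#
# Complete design:  cov(vec(Y)) = Cs (x) Rs + Cn (x) I_N, with the fixed
# effects F B profiled out by generalized least squares at every parameter
# value.  A one-off SVD of G/sqrt(S) reduces every objective evaluation to
# operations on the top rank(Rs) individual coordinates plus Gram-matrix
# corrections for the null space, so the per-evaluation cost does not grow
# with N.  Stratified design: a low-rank (<= C*S) plus diagonal Woodbury
# representation with per-context Gram precomputations.

# ---------------------------------------------------------------------------
# precomputation
# ---------------------------------------------------------------------------

.regionPrecompute <- function(design, region) {
  stopifnot(is(design, "StudyDesign"), is(region, "RegionGenotypes"))
  N <- designN(design)
  if (nrow(region@G) != N)
    stop("design and region must share the same individuals (and ordering)")
  F <- design@F
  K <- ncol(F)
  Ghat <- region@G / sqrt(region@S)
  if (design@layout == "complete") {
    sv <- svd(Ghat, nv = 0)
    keep <- sv$d > 1e-9 * max(sv$d[1], 1)
    U1 <- sv$u[, keep, drop = FALSE]
    d <- sv$d[keep]^2
    Y <- design@Y
    list(layout = "complete", N = N, C = design@nContexts, K = K,
         d = d, U1 = U1, Ghat = Ghat,
         P = crossprod(U1, Y), Q = crossprod(U1, F),
         YtY = crossprod(Y), FtF = crossprod(F), FtY = crossprod(F, Y),
         Y = Y, F = F)
  } else {
    C <- design@nContexts
    S <- region@S
    idx <- split(seq_len(N), factor(design@context, levels = seq_len(C)))
    H <- GtF <- Gty <- FtFl <- Ftyl <- vector("list", C)
    yty <- Na <- numeric(C)
    for (a in seq_len(C)) {
      ia <- idx[[a]]
      Ga <- Ghat[ia, , drop = FALSE]
      Fa <- F[ia, , drop = FALSE]
      ya <- design@y[ia]
      H[[a]] <- crossprod(Ga)
      GtF[[a]] <- crossprod(Ga, Fa)
      Gty[[a]] <- as.numeric(crossprod(Ga, ya))
      FtFl[[a]] <- crossprod(Fa)
      Ftyl[[a]] <- as.numeric(crossprod(Fa, ya))
      yty[a] <- sum(ya^2)
      Na[a] <- length(ia)
    }
    list(layout = "stratified", N = N, C = C, K = K, S = S,
         H = H, GtF = GtF, Gty = Gty, FtFl = FtFl, Ftyl = Ftyl,
         yty = yty, Na = Na, idx = idx, Ghat = Ghat,
         y = design@y, context = design@context, F = F)
  }
}

# Replace the phenotype side of a precompute (used for bootstrap replicates).
.preWithY <- function(pre, Ynew) {
  if (pre$layout == "complete") {
    pre$P <- crossprod(pre$U1, Ynew)
    pre$YtY <- crossprod(Ynew)
    pre$FtY <- crossprod(pre$F, Ynew)
    pre$Y <- Ynew
  } else {
    for (a in seq_along(pre$idx)) {
      ia <- pre$idx[[a]]
      ya <- Ynew[ia]
      pre$Gty[[a]] <- as.numeric(crossprod(pre$Ghat[ia, , drop = FALSE], ya))
      pre$Ftyl[[a]] <- as.numeric(crossprod(pre$F[ia, , drop = FALSE], ya))
      pre$yty[a] <- sum(ya^2)
    }
    pre$y <- Ynew
  }
  pre
}

# Permute the genotype rows relative to the phenotypes (mtSet permutations).
.preWithPermutedG <- function(pre, perm) {
  if (pre$layout == "complete") {
    # G*[i,] = G[perm[i],] so Rs* = Rs[perm, perm] and U* = U1[perm, ]
    U1p <- pre$U1[perm, , drop = FALSE]
    pre$U1 <- U1p
    pre$P <- crossprod(U1p, pre$Y)
    pre$Q <- crossprod(U1p, pre$F)
    pre
  } else {
    Gp <- pre$Ghat[perm, , drop = FALSE]
    pre$Ghat <- Gp
    for (a in seq_along(pre$idx)) {
      ia <- pre$idx[[a]]
      Ga <- Gp[ia, , drop = FALSE]
      pre$H[[a]] <- crossprod(Ga)
      pre$GtF[[a]] <- crossprod(Ga, pre$F[ia, , drop = FALSE])
      pre$Gty[[a]] <- as.numeric(crossprod(Ga, pre$y[ia]))
    }
    pre
  }
}

.modelPtr <- function(pre, kind) {
  code <- kindCode(kind)
  if (pre$layout == "complete") {
    cpp_complete_new(pre$d, pre$P, pre$Q, pre$YtY, pre$FtF, pre$FtY,
                     pre$N, code)
  } else {
    cpp_strat_new(pre$H, pre$GtF, pre$Gty, pre$FtFl, pre$Ftyl,
                  pre$yty, pre$Na, pre$N, pre$K, pre$S, code)
  }
}

.negll <- function(pre, ptr, theta) {
  if (pre$layout == "complete") cpp_complete_negll(ptr, theta)
  else cpp_strat_negll(ptr, theta)
}

.grad <- function(pre, ptr, theta) {
  if (pre$layout == "complete") cpp_complete_grad(ptr, theta)
  else cpp_strat_grad(ptr, theta)
}

.fitted <- function(pre, ptr, theta) {
  if (pre$layout == "complete") cpp_complete_fitted(ptr, theta)
  else cpp_strat_fitted(ptr, theta)
}

.nParN <- function(C, layout) {
  if (layout == "complete") as.integer(C * (C + 1) / 2) else as.integer(C)
}

# ---------------------------------------------------------------------------
# public objective
# ---------------------------------------------------------------------------

#' Efficient negative restricted log-likelihood
#'
#' Evaluates the REML objective of the interaction set model for a given
#' covariance structure and parameter vectors.  The complete-design path
#' uses a Kronecker diagonalization after a one-off factorization of the
#' region genotypes; the stratified path uses a low-rank plus diagonal
#' representation.  Both have per-evaluation cost linear (or better) in N.
#'
#' @param design a \linkS4class{StudyDesign}.
#' @param region a \linkS4class{RegionGenotypes} (same individuals, same order).
#' @param covKind structure of Cs: "null", "block", "rank1" or "full".
#' @param thetaS free parameters of Cs (length depends on covKind).
#' @param thetaN free parameters of Cn: the C(C+1)/2 lower-triangular factor
#'   entries with log-diagonal (complete) or C log-standard-deviations
#'   (stratified; Cn is restricted to its diagonal, whose off-diagonal
#'   entries never enter the stratified likelihood).
#' @param gradient return the analytic (complete) or central-difference
#'   (stratified) gradient as attribute "gradient".
#' @return the negative restricted log-likelihood (scalar).
#' @export
remlObjective <- function(design, region, covKind, thetaS, thetaN,
                          gradient = FALSE) {
  covKind <- match.arg(covKind, covKinds)
  theta <- c(thetaS, thetaN)
  if (any(!is.finite(theta))) stop("non-finite parameters")
  pre <- .regionPrecompute(design, region)
  stopifnot(length(thetaS) == nParS(covKind, pre$C),
            length(thetaN) == .nParN(pre$C, pre$layout))
  ptr <- .modelPtr(pre, covKind)
  val <- .negll(pre, ptr, theta)
  if (gradient) attr(val, "gradient") <- .grad(pre, ptr, theta)
  val
}

# ---------------------------------------------------------------------------
# dense oracle
# ---------------------------------------------------------------------------

#' Dense REML oracle (testing reference)
#'
#' Builds the full (N*C) x (N*C) covariance (complete design) or N x N
#' covariance (stratified) explicitly and evaluates the identical REML
#' objective by direct factorization.  Used as an independent reference for
#' the efficient path; guarded to small problems.
#'
#' @inheritParams remlObjective
#' @param Cs,Cn optional explicit covariance matrices, overriding
#'   covKind/thetaS/thetaN.
#' @return the negative restricted log-likelihood.
#' @export
denseOracle <- function(design, region, covKind = "full",
                        thetaS = NULL, thetaN = NULL, Cs = NULL, Cn = NULL) {
  N <- designN(design)
  C <- design@nContexts
  if (N * C > 500) stop("dense oracle restricted to N*C <= 500")
  if (is.null(Cs)) Cs <- csFromTheta(thetaS, match.arg(covKind, covKinds), C)
  if (is.null(Cn)) Cn <- cnFromTheta(thetaN, C, design@layout)
  Rs <- region@Rs
  F <- design@F
  K <- ncol(F)
  if (design@layout == "complete") {
    V <- kronecker(Cs, Rs) + kronecker(Cn, diag(N))
    X <- if (K > 0) kronecker(diag(C), F) else matrix(0, N * C, 0)
    y <- as.vector(design@Y)
  } else {
    ctx <- design@context
    V <- Cs[ctx, ctx] * Rs + diag(diag(Cn)[ctx], N)
    X <- matrix(0, N, K * C)
    for (a in seq_len(C)) {
      rows <- which(ctx == a)
      X[rows, (a - 1) * K + seq_len(K)] <- F[rows, , drop = FALSE]
    }
    y <- design@y
  }
  .gaussREML(y, X, V)
}

.gaussREML <- function(y, X, V) {
  n <- length(y)
  p <- ncol(X)
  ch <- chol(V)
  logdetV <- 2 * sum(log(diag(ch)))
  Viy <- backsolve(ch, forwardsolve(t(ch), y))
  if (p > 0) {
    ViX <- backsolve(ch, forwardsolve(t(ch), X))
    A <- crossprod(X, ViX)
    b <- as.numeric(crossprod(X, Viy))
    beta <- solve(A, b)
    q <- sum(y * Viy) - sum(b * beta)
    logdetA <- as.numeric(determinant(A, logarithm = TRUE)$modulus)
  } else {
    q <- sum(y * Viy)
    logdetA <- 0
  }
  0.5 * ((n - p) * log(2 * pi) + logdetV + logdetA + q)
}

# ---------------------------------------------------------------------------
# fitting
# ---------------------------------------------------------------------------

.momentStart <- function(pre, kind) {
  C <- pre$C
  if (pre$layout == "complete") {
    R <- pre$Y
    if (pre$K > 0) R <- qr.resid(qr(pre$F), pre$Y)
    Ce <- crossprod(R) / max(1, pre$N - pre$K)
    Ce <- Ce + diag(1e-4, C)
    Cn0 <- 0.9 * Ce
    Cs0 <- 0.1 * Ce
    thN <- packLower(t(chol(Cn0)), logDiag = TRUE)
  } else {
    v <- numeric(C)
    for (a in seq_len(C)) {
      ia <- pre$idx[[a]]
      r <- pre$y[ia]
      if (pre$K > 0) r <- qr.resid(qr(pre$F[ia, , drop = FALSE]), r)
      v[a] <- max(stats::var(r), 1e-4)
    }
    Cs0 <- 0.1 * mean(v) * (diag(0.5, C) + matrix(0.5, C, C))
    thN <- 0.5 * log(0.9 * v)
  }
  thS <- switch(kind,
                null  = numeric(0),
                block = sqrt(max(mean(Cs0), 1e-6)),
                rank1 = {
                  ev <- eigen(Cs0, symmetric = TRUE)
                  ev$vectors[, 1] * sqrt(max(ev$values[1], 1e-6))
                },
                full  = packLower(t(chol(Cs0 + diag(1e-8, C)))))
  c(thS, thN)
}

.restartStarts <- function(pre, kind, restarts, seed) {
  base <- .momentStart(pre, kind)
  starts <- list(base)
  if (restarts > 1) {
    withSeed(childSeed(seed, 7L), {
      for (r in seq_len(restarts - 1)) {
        starts[[r + 1]] <- base * (1 + 0.4 * rnorm(length(base))) +
          0.1 * rnorm(length(base))
      }
    })
  }
  starts
}

#' Fit the interaction set model by constrained REML
#'
#' Minimizes the REML objective over the free covariance parameters with
#' L-BFGS-B quasi-Newton iterations from multiple starts: a moment-based
#' start from the empirical trait covariance plus seeded perturbed restarts.
#' Fixed effects are profiled out by generalized least squares.
#'
#' @inheritParams remlObjective
#' @param options list: \code{restarts} (default 3), \code{gradTol}
#'   (projected-gradient tolerance, default 1e-5), \code{maxEvals} (default
#'   500), \code{seed} (restart stream, default 1).
#' @return A \linkS4class{FittedModel}.
#' @export
fitModel <- function(design, region, covKind, options = list()) {
  pre <- .regionPrecompute(design, region)
  .fitFromPre(pre, match.arg(covKind, covKinds), options)
}

.fitFromPre <- function(pre, kind, options = list()) {
  o <- modifyList(list(restarts = 3L, gradTol = 1e-5, maxEvals = 500L,
                       seed = 1L), options)
  ptr <- .modelPtr(pre, kind)
  fn <- function(th) .negll(pre, ptr, th)
  gr <- function(th) .grad(pre, ptr, th)
  starts <- .restartStarts(pre, kind, o$restarts, o$seed)
  best <- NULL
  nev <- 0L
  bestRestart <- 1L
  anyConv <- FALSE
  for (r in seq_along(starts)) {
    res <- tryCatch(
      optim(starts[[r]], fn, gr, method = "L-BFGS-B",
            lower = -30, upper = 30,
            control = list(maxit = o$maxEvals, pgtol = o$gradTol,
                           factr = 1e7)),
      error = function(e) NULL)
    if (is.null(res)) next
    nev <- nev + res$counts[1]
    conv <- res$convergence == 0 && res$value < 1e9
    anyConv <- anyConv || conv
    if (is.null(best) || res$value < best$value) {
      best <- res
      bestRestart <- r
    }
  }
  if (is.null(best))
    stop("all optimizer restarts failed")
  ft <- .fitted(pre, ptr, best$par)
  C <- pre$C
  ps <- nParS(kind, C)
  Cn <- if (pre$layout == "complete") ft$Cn else diag(as.numeric(ft$Cn), C)
  new("FittedModel", kind = kind, layout = pre$layout,
      Cs = ft$Cs, Cn = Cn, B = ft$B,
      thetaS = as.numeric(best$par[seq_len(ps)]),
      thetaN = as.numeric(best$par[(ps + 1):length(best$par)]),
      logLik = -ft$negll, converged = anyConv,
      nEvals = as.integer(nev), restart = as.integer(bestRestart))
}

# ---------------------------------------------------------------------------
# sampling from a fitted model
# ---------------------------------------------------------------------------

#' Sample phenotype replicates from a fitted model
#'
#' Draws from N(vec(F B), Cs (x) Rs + Cn (x) I) in the complete layout, or
#' from the stratified analogue, using the generative low-rank form
#' Y* = F B + (G/sqrt(S)) Zw Ls' + Zn Ln' so no N x N factorization is
#' required.  Deterministic given the seed.
#'
#' @param fitted a converged \linkS4class{FittedModel}.
#' @param design the \linkS4class{StudyDesign} that was fitted.
#' @param region the \linkS4class{RegionGenotypes} that was fitted.
#' @param seed RNG seed.
#' @return a \linkS4class{StudyDesign} replicate with the same layout.
#' @export
samplePhenotypes <- function(fitted, design, region, seed = 1L) {
  stopifnot(is(fitted, "FittedModel"))
  if (!fitted@converged) stop("refusing to sample from a non-converged fit")
  pre <- .regionPrecompute(design, region)
  Ynew <- .sampleFromFit(pre, fitted, seed)
  if (design@layout == "complete") completeDesign(Ynew, design@F)
  else stratifiedDesign(Ynew, design@context, design@F, design@nContexts)
}

.covFactor <- function(Cmat) {
  ev <- eigen((Cmat + t(Cmat)) / 2, symmetric = TRUE)
  if (min(ev$values) < -1e-6) stop("fitted covariance is not positive semidefinite")
  keep <- ev$values > 1e-12
  if (!any(keep)) return(matrix(0, nrow(Cmat), 0))
  ev$vectors[, keep, drop = FALSE] %*% diag(sqrt(ev$values[keep]), sum(keep))
}

.sampleFromFit <- function(pre, fitted, seed) {
  N <- pre$N
  C <- pre$C
  S <- ncol(pre$Ghat)
  Ls <- .covFactor(fitted@Cs)
  withSeed(seed, {
    U <- if (ncol(Ls) > 0)
      pre$Ghat %*% (matrix(rnorm(S * ncol(Ls)), S) %*% t(Ls))
    else matrix(0, N, C)
    if (pre$layout == "complete") {
      Ln <- t(chol((fitted@Cn + t(fitted@Cn)) / 2))
      Yn <- matrix(rnorm(N * C), N) %*% t(Ln)
      mu <- if (pre$K > 0) pre$F %*% fitted@B else matrix(0, N, C)
      mu + U + Yn
    } else {
      ctx <- pre$context
      dn <- diag(fitted@Cn)
      mu <- if (pre$K > 0) rowSums(pre$F * t(fitted@B)[ctx, , drop = FALSE])
            else numeric(N)
      mu + U[cbind(seq_len(N), ctx)] + sqrt(dn[ctx]) * rnorm(N)
    }
  })
}
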