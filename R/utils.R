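# Internal helpers: deterministic seed streams and covariance parameter packing.

# Derive a child seed from a base seed and a path of small integer indices.
# Multiplicative-congruential mixing keeps everything exactly representable
# in doubles and below 2^31, so streams are reproducible across platforms
# and independent of execution order (e.g. under chunked scans).
childSeed <- function(seed, ...) {
  ix <- c(...)
  s <- as.double(seed %% 2147483647L)
  for (i in ix) s <- (s * 48271 + as.double(i) + 1) %% 2147483647
  as.integer(s)
}

# Evaluate expr under a temporary RNG state seeded with `seed`.
withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE))
    get(".Random.seed", envir = .GlobalEnv) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = .GlobalEnv)
    else suppressWarnings(rm(".Random.seed", envir = .GlobalEnv))
  })
  set.seed(as.integer(seed %% 2147483647L))
  expr
}

covKinds <- c("null", "block", "rank1", "full")

kindCode <- function(kind) {
  match.arg(kind, covKinds)
  match(kind, covKinds) - 1L
}

nParS <- function(kind, C) {
  switch(kind,
         null  = 0L,
         block = 1L,
         rank1 = as.integer(C),
         full  = as.integer(C * (C + 1) / 2),
         stop("unknown covariance kind: ", kind))
}

# column-major lower-triangle fill, optionally exponentiating the diagonal
lowerFill <- function(theta, C, expDiag = FALSE) {
  L <- matrix(0, C, C)
  idx <- which(lower.tri(L, diag = TRUE))
  stopifnot(length(theta) == length(idx))
  L[idx] <- theta
  if (expDiag) diag(L) <- exp(diag(L))
  L
}

packLower <- function(L, logDiag = FALSE) {
  if (logDiag) diag(L) <- log(pmax(diag(L), 1e-12))
  L[lower.tri(L, diag = TRUE)]
}

csFromTheta <- function(theta, kind, C) {
  switch(kind,
         null  = matrix(0, C, C),
         block = matrix(theta[1]^2, C, C),
         rank1 = tcrossprod(theta),
         full  = tcrossprod(lowerFill(theta, C)))
}

cnFromTheta <- function(theta, C, layout = "complete") {
  if (layout == "complete") {
    tcrossprod(lowerFill(theta, C, expDiag = TRUE))
  } else {
    diag(exp(2 * theta), nrow = C)
  }
}

scaleToVar <- function(x, targetVar) {
  s <- stats::sd(x)
  if (s < 1e-300) stop("cannot rescale a (near-)constant component")
  (x - mean(x)) / s * sqrt(targetVar)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
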