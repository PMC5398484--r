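# Shared fixtures, built in code and memoized for the duration of the run.

.fixtureCache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixtureCache)) assign(key, expr, envir = .fixtureCache)
  get(key, envir = .fixtureCache)
}

# small mosaic region + standardization, N individuals
smallRegion <- function(N = 200, S = 40, seed = 11) {
  cached(sprintf("region_%d_%d_%d", N, S, seed), {
    co <- simulateMosaicCohort(N, nVariants = S, regionLengthBp = 10000L,
                               seed = seed)
    standardizeRegion(co)
  })
}

# tiny random region for oracle-scale problems (no LD machinery)
tinyRegion <- function(N, S, seed) {
  withr::with_seed(seed, {
    p <- runif(S, 0.1, 0.5)
    d <- matrix(rbinom(N * S, 2, rep(p, each = N)), N, S)
    # guard monomorphic draws
    for (v in seq_len(S)) if (sd(d[, v]) < 1e-12) d[1, v] <- 2 - d[1, v]
    standardizeRegion(DosageMatrix(d, positions = seq_len(S) * 10), mafMin = 0)
  })
}

randomCompleteDesign <- function(N, C = 2, K = 1, seed = 1) {
  withr::with_seed(seed, {
    F <- if (K == 0) matrix(0, N, 0)
         else cbind(1, matrix(rnorm(N * (K - 1)), N, K - 1))[, seq_len(K), drop = FALSE]
    completeDesign(matrix(rnorm(N * C), N, C), F)
  })
}

randomStratifiedDesign <- function(N, C = 2, K = 1, seed = 1) {
  withr::with_seed(seed, {
    ctx <- c(rep(seq_len(C), 2), sample(seq_len(C), N - 2 * C, TRUE))
    F <- if (K == 0) matrix(0, N, 0)
         else cbind(1, matrix(rnorm(N * (K - 1)), N, K - 1))[, seq_len(K), drop = FALSE]
    stratifiedDesign(rnorm(N), ctx, F, C)
  })
}

randomTheta <- function(kind, C = 2, layout = "complete", seed = 1) {
  withr::with_seed(seed, {
    ps <- iSetR:::nParS(kind, C)
    pn <- if (layout == "complete") C * (C + 1) / 2 else C
    list(thetaS = rnorm(ps), thetaN = 0.4 * rnorm(pn))
  })
}

# run the three tests plus iSet/iSet-het bootstrap nulls over simulated
# regions and return the pooled empirical p-value table
calibrationRun <- function(nRegions, J, N = 1000, seedBase = 1,
                           configFun = function(i) simulationConfig(seed = seedBase * 10000 + i),
                           tests = c("iSet", "iSetHet"),
                           transformY = identity,
                           nVariants = 120L, regionLengthBp = 30000L) {
  res <- vector("list", nRegions)
  nul <- vector("list", nRegions)
  for (i in seq_len(nRegions)) {
    co <- simulateMosaicCohort(N, nVariants = nVariants,
                               regionLengthBp = regionLengthBp,
                               seed = seedBase * 1000 + i)
    rg <- standardizeRegion(co)
    bb <- simulatePhenotypes(configFun(i), rg)
    Y <- transformY(phenotypes(bb))
    dd <- completeDesign(Y)
    pre <- iSetR:::.regionPrecompute(dd, rg)
    res[[i]] <- iSetR:::.testFromPre(pre, paste0("w", i), list(restarts = 2))
    nul[[i]] <- iSetR:::.nullsFromPre(pre, as.integer(J),
                                      iSetR:::childSeed(seedBase, i), tests,
                                      list(restarts = 2))
  }
  poolAndPValues(res, makeNullPool(nul))
}

expect_within <- function(x, lo, hi, label = deparse(substitute(x))) {
  expect_true(x >= lo && x <= hi,
              label = sprintf("%s = %.4g in [%.4g, %.4g]", label, x, lo, hi))
}
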