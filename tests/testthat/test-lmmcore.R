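test_that("materializeCovariance produces the structured matrices", {
  expect_equal(materializeCovariance(traitContextCovariance("block", 0)),
               matrix(0, 2, 2))
  expect_equal(materializeCovariance(traitContextCovariance("rank1", c(1, 1))),
               matrix(1, 2, 2))
  expect_equal(materializeCovariance(traitContextCovariance("full", c(1, 0, 1))),
               diag(2))
  expect_equal(materializeCovariance(traitContextCovariance("null", C = 3)),
               matrix(0, 3, 3))
  expect_error(traitContextCovariance("rank1", 1), "length")
  # PSD by construction for random parameters, all kinds
  for (i in 1:20) {
    kind <- c("block", "rank1", "full")[1 + i %% 3]
    th <- randomTheta(kind, seed = i)
    M <- materializeCovariance(traitContextCovariance(kind, th$thetaS))
    expect_gte(min(eigen(M, symmetric = TRUE, only.values = TRUE)$values), -1e-12)
  }
})

test_that("REML objective at the standard-normal point is the exact Gaussian constant", {
  rg <- tinyRegion(3, 3, seed = 1)
  des <- completeDesign(matrix(0, 3, 2), matrix(0, 3, 0))
  v <- remlObjective(des, rg, "null", numeric(0), c(0, 0, 0))
  expect_equal(as.numeric(v), 0.5 * 6 * log(2 * pi), tolerance = 1e-12)
})

test_that("efficient REML path equals the dense oracle on random instances (both layouts, all kinds)", {
  worst <- 0
  for (i in 1:25) {
    N <- 6 + (i %% 7)
    rg <- tinyRegion(N, 3 + (i %% 4), seed = 100 + i)
    des <- randomCompleteDesign(N, K = i %% 3, seed = 200 + i)
    for (kind in c("null", "block", "rank1", "full")) {
      th <- randomTheta(kind, seed = 300 + i)
      a <- as.numeric(remlObjective(des, rg, kind, th$thetaS, th$thetaN))
      b <- denseOracle(des, rg, kind, th$thetaS, th$thetaN)
      worst <- max(worst, abs(a - b))
    }
  }
  for (i in 1:25) {
    N <- 9 + (i %% 8)
    rg <- tinyRegion(N, 3 + (i %% 4), seed = 400 + i)
    des <- randomStratifiedDesign(N, K = 1 + i %% 2, seed = 500 + i)
    for (kind in c("null", "block", "rank1", "full")) {
      th <- randomTheta(kind, layout = "stratified", seed = 600 + i)
      a <- as.numeric(remlObjective(des, rg, kind, th$thetaS, th$thetaN))
      b <- denseOracle(des, rg, kind, th$thetaS, th$thetaN)
      worst <- max(worst, abs(a - b))
    }
  }
  expect_lt(worst, 1e-8)
})

test_that("dense oracle is invariant to joint relabeling and obeys the Gaussian scaling identity", {
  N <- 8
  rg <- tinyRegion(N, 4, seed = 3)
  des <- randomCompleteDesign(N, K = 1, seed = 4)
  th <- randomTheta("full", seed = 5)
  v0 <- denseOracle(des, rg, "full", th$thetaS, th$thetaN)
  perm <- withr::with_seed(9, sample(N))
  rgP <- new("RegionGenotypes", G = rg@G[perm, , drop = FALSE], S = rg@S,
             Rs = rg@Rs[perm, perm], ids = rg@ids, positions = rg@positions,
             chrom = rg@chrom)
  desP <- completeDesign(des@Y[perm, , drop = FALSE], des@F[perm, , drop = FALSE])
  expect_equal(denseOracle(desP, rgP, "full", th$thetaS, th$thetaN), v0,
               tolerance = 1e-9)

  # scaling y by 2 with Cs, Cn scaled by 4 shifts the REML value by the
  # Jacobian term (n - p) * log(2)
  Cs <- iSetR:::csFromTheta(th$thetaS, "full", 2)
  Cn <- iSetR:::cnFromTheta(th$thetaN, 2)
  des2 <- completeDesign(2 * des@Y, des@F)
  v2 <- denseOracle(des2, rg, Cs = 4 * Cs, Cn = 4 * Cn)
  n <- 2 * N; p <- 2 * ncol(des@F)
  expect_equal(v2 - v0, (n - p) * log(2), tolerance = 1e-9)
})

test_that("stratified likelihood never sees off-diagonal Cn entries", {
  N <- 12
  rg <- tinyRegion(N, 4, seed = 6)
  des <- randomStratifiedDesign(N, K = 1, seed = 7)
  Cs <- iSetR:::csFromTheta(c(0.5, 0.2), "rank1", 2)
  Cn <- diag(c(0.8, 1.2))
  CnOff <- Cn; CnOff[1, 2] <- CnOff[2, 1] <- 0.5
  expect_identical(denseOracle(des, rg, Cs = Cs, Cn = Cn),
                   denseOracle(des, rg, Cs = Cs, Cn = CnOff))
})

test_that("analytic gradient of the complete-design objective matches finite differences", {
  N <- 40
  rg <- tinyRegion(N, 6, seed = 8)
  des <- randomCompleteDesign(N, K = 2, seed = 9)
  for (kind in c("null", "block", "rank1", "full")) {
    th <- randomTheta(kind, seed = 20 + nchar(kind))
    g <- attr(remlObjective(des, rg, kind, th$thetaS, th$thetaN,
                            gradient = TRUE), "gradient")
    thAll <- c(th$thetaS, th$thetaN)
    ps <- iSetR:::nParS(kind, 2)
    fd <- vapply(seq_along(thAll), function(t) {
      h <- 1e-6 * max(1, abs(thAll[t]))
      tp <- thAll; tp[t] <- tp[t] + h
      tm <- thAll; tm[t] <- tm[t] - h
      (as.numeric(remlObjective(des, rg, kind, head(tp, ps), tail(tp, 3))) -
       as.numeric(remlObjective(des, rg, kind, head(tm, ps), tail(tm, 3)))) / (2 * h)
    }, 0)
    expect_equal(as.numeric(g), fd, tolerance = 1e-5)
  }
})

test_that("fitting recovers a block covariance and respects nesting and variance bounds", {
  N <- 2000
  rg <- smallRegion(N, 60, seed = 35)
  withr::with_seed(10, {
    Zw <- matrix(rnorm(nVariants(rg)), ncol = 1)
    u <- (genotypes(rg) / sqrt(nVariants(rg))) %*% Zw %*% sqrt(0.5) %*% t(c(1, 1))
    Y <- u + matrix(rnorm(N * 2), N)
  })
  des <- completeDesign(Y)
  fit <- fitModel(des, rg, "block")
  expect_true(fit@converged)
  expect_within(fit@Cs[1, 1], 0.4, 0.6)

  # nested model spaces: REML log-likelihood non-decreasing
  lls <- vapply(c("null", "block", "rank1", "full"), function(k)
    fitModel(des, rg, k)@logLik, 0)
  expect_true(all(diff(lls) >= -1e-6))

  # pure-noise data: fitted full Cs cannot exceed the empirical trait variance
  desN <- randomCompleteDesign(500, seed = 11)
  rgN <- smallRegion(500, 40, seed = 36)
  fitN <- fitModel(desN, rgN, "full")
  expect_lte(sum(diag(fitN@Cs)), sum(diag(cov(desN@Y))) + 1e-6)
})

test_that("Frobenius error of the fitted Cs shrinks with sample size", {
  CsTrue <- matrix(c(0.4, 0.1, 0.1, 0.3), 2)
  A <- t(chol(CsTrue))
  err <- vapply(c(200, 2000), function(N) {
    rg <- smallRegion(N, 40, seed = 37)
    mean(vapply(1:3, function(r) {
      withr::with_seed(500 + N + r, {
        S <- nVariants(rg)
        U <- (genotypes(rg) / sqrt(S)) %*% (matrix(rnorm(S * 2), S) %*% t(A))
        Y <- U + matrix(rnorm(N * 2), N)
      })
      f <- fitModel(completeDesign(Y), rg, "full")
      sqrt(sum((f@Cs - CsTrue)^2))
    }, 0))
  }, 0)
  expect_lt(err[2], err[1])
})

test_that("sampled phenotype replicates match the fitted model", {
  N <- 4
  rg <- tinyRegion(N, 3, seed = 12)
  des <- randomCompleteDesign(N, K = 0, seed = 13)
  fit <- new("FittedModel", kind = "full", layout = "complete",
             Cs = matrix(c(0.5, 0.2, 0.2, 0.4), 2), Cn = diag(2),
             B = matrix(0, 0, 2), thetaS = numeric(4), thetaN = numeric(3),
             logLik = 0, converged = TRUE, nEvals = 0L, restart = 1L)
  draws <- vapply(1:5000, function(i)
    as.vector(iSetR:::.sampleFromFit(iSetR:::.regionPrecompute(des, rg), fit, i)),
    numeric(N * 2))
  Kth <- kronecker(fit@Cs, relatedness(rg)) + kronecker(fit@Cn, diag(N))
  Kemp <- cov(t(draws))
  expect_lt(max(abs(Kemp - Kth)), 0.1)
  expect_lt(max(abs(rowMeans(draws))), 0.1)

  # null model: entries are iid standard normal
  fit0 <- new("FittedModel", kind = "null", layout = "complete",
              Cs = matrix(0, 2, 2), Cn = diag(2), B = matrix(0, 0, 2),
              thetaS = numeric(0), thetaN = numeric(3), logLik = 0,
              converged = TRUE, nEvals = 0L, restart = 1L)
  rg2 <- tinyRegion(2500, 3, seed = 14)
  des2 <- randomCompleteDesign(2500, K = 0, seed = 15)
  z <- as.vector(iSetR:::.sampleFromFit(iSetR:::.regionPrecompute(des2, rg2),
                                        fit0, 7))
  expect_gt(ks.test(z, "pnorm")$p.value, 0.01)
})

test_that("per-evaluation cost after precomputation does not grow with N (complete design)", {
  timeEval <- function(N) {
    rg <- smallRegion(N, 40, seed = 38)
    des <- randomCompleteDesign(N, K = 2, seed = 39)
    pre <- iSetR:::.regionPrecompute(des, rg)
    ptr <- iSetR:::.modelPtr(pre, "full")
    th <- c(randomTheta("full", seed = 40)$thetaS,
            randomTheta("full", seed = 40)$thetaN)
    iSetR:::.negll(pre, ptr, th)  # warm up
    t0 <- Sys.time()
    for (i in 1:200) iSetR:::.negll(pre, ptr, th)
    as.numeric(Sys.time() - t0, units = "secs")
  }
  t500 <- timeEval(500)
  t4000 <- timeEval(4000)
  # rank(Rs) <= S = 40 in both cases, so cost is N-independent; allow broad
  # slack for machine noise while excluding quadratic growth (64x)
  expect_lt(t4000, 8 * max(t500, 0.005))
})
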