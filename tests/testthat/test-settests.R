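test_that("region test statistics are non-negative with boundary mass under persistent effects", {
  llrs <- vapply(1:12, function(i) {
    rg <- smallRegion(400, 50, seed = 70 + i)
    b <- simulatePhenotypes(simulationConfig(seed = 700 + i), rg)
    testRegion(completeDesign(phenotypes(b)), rg,
               options = list(restarts = 2))@llr
  }, numeric(3))
  expect_true(all(llrs >= 0))
  # PSD constraint puts positive probability mass exactly at zero
  expect_gt(sum(llrs["iSet", ] == 0 | llrs["iSetHet", ] == 0), 0)
})

test_that("null LLR draws have the right shape and leave Y untouched", {
  rg <- smallRegion(200, 40, seed = 81)
  b <- simulatePhenotypes(simulationConfig(seed = 81), rg)
  des <- completeDesign(phenotypes(b))
  Ybefore <- des@Y
  nul <- drawNullLLRs(des, rg, J = 8, seed = 3, options = list(restarts = 1))
  expect_identical(des@Y, Ybefore)
  expect_named(nul, c("mtSet", "iSet", "iSetHet"))
  expect_true(all(lengths(nul) == 8L))
  expect_true(all(unlist(nul) >= 0))
  nul2 <- drawNullLLRs(des, rg, J = 8, seed = 3, options = list(restarts = 1))
  expect_identical(nul, nul2)
})

test_that("empirical p-values obey the pooled-null formula, floor and toy-grid uniformity", {
  mk <- function(llr) new("RegionTestResult", regionId = "r", fits = list(),
                          llr = c(mtSet = llr, iSet = llr, iSetHet = llr),
                          converged = c(full = TRUE))
  pool <- new("NullPool", llr = list(mtSet = c(1, 2, 3, 4), iSet = c(1, 2, 3, 4),
                                     iSetHet = c(1, 2, 3, 4)),
              J = 2L, T = 2L, provenance = data.frame())
  # observed above every pooled null: p attains the floor 1/(J*T + 1)
  expect_equal(poolAndPValues(list(mk(10)), pool)$p_mtSet, 1 / 5)
  # observed at zero with an all-positive pool: p = 1
  expect_equal(poolAndPValues(list(mk(0)), pool)$p_iSet, 1)
  # ties count as exceedances
  expect_equal(poolAndPValues(list(mk(3)), pool)$p_iSet, 3 / 5)

  # exhaustive 5-region, J = 4 toy pool with uniform ranks
  obs <- c(0.5, 1.5, 2.5, 3.5, 4.5)
  results <- lapply(obs, mk)
  toy <- new("NullPool",
             llr = list(mtSet = rep(0:4, 4)[1:20], iSet = rep(0:4, 4)[1:20],
                        iSetHet = rep(0:4, 4)[1:20]),
             J = 4L, T = 5L, provenance = data.frame())
  p <- poolAndPValues(results, toy)$p_mtSet
  expect_equal(p, (1 + c(16, 12, 8, 4, 0)) / 21)
  expect_error(poolAndPValues(list(mk(1)),
                              new("NullPool", llr = list(mtSet = numeric(0)),
                                  J = 0L, T = 0L, provenance = data.frame())),
               "empty null pool")
})

test_that("observed LLR is exchangeable with its own bootstrap null under persistent effects", {
  # rank of the observed iSet LLR within its region's null draws is uniform
  J <- 12
  ranks <- vapply(1:60, function(i) {
    rg <- smallRegion(250, 40, seed = 90 + i)
    b <- simulatePhenotypes(simulationConfig(seed = 900 + i), rg)
    des <- completeDesign(phenotypes(b))
    pre <- iSetR:::.regionPrecompute(des, rg)
    obs <- iSetR:::.testFromPre(pre, "r", list(restarts = 2))@llr["iSet"]
    nul <- iSetR:::.nullsFromPre(pre, J, iSetR:::childSeed(17, i), "iSet",
                                 list(restarts = 2))$iSet
    sum(nul < obs) + 1
  }, 0)
  tab <- tabulate(ceiling(ranks / ((J + 1) / 4)), 4)
  expect_gt(chisq.test(tab)$p.value, 0.01)
})

test_that("strong negative rescaling drives iSet above its persistent null", {
  nullLLR <- vapply(1:40, function(i) {
    rg <- smallRegion(500, 50, seed = 120 + i)
    b <- simulatePhenotypes(simulationConfig(seed = 1200 + i), rg)
    testRegion(completeDesign(phenotypes(b)), rg,
               options = list(restarts = 2))@llr["iSet"]
  }, 0)
  thr <- quantile(nullLLR, 0.99)
  altLLR <- vapply(1:30, function(i) {
    rg <- smallRegion(500, 50, seed = 160 + i)
    b <- simulatePhenotypes(simulationConfig(architecture = "rescaling",
                                             proportionality = -1,
                                             regionVariance = 0.1,
                                             seed = 1600 + i), rg)
    testRegion(completeDesign(phenotypes(b)), rg,
               options = list(restarts = 2))@llr["iSet"]
  }, 0)
  expect_gte(mean(altLLR > thr), 0.9)
})

test_that("three-locus scan attributes the largest iSet-het statistic to the heterogeneity locus", {
  hits <- vapply(1:8, function(i) {
    b <- simulateIllustrationRegion(seed = 400 + i, nIndividuals = 600)
    loci <- attr(b@components, "loci")
    des <- completeDesign(phenotypes(b))
    het <- vapply(1:3, function(k) {
      keep <- which(b@region@positions >= loci$start[k] &
                    b@region@positions < loci$end[k])
      G <- b@region@G[, keep, drop = FALSE]
      sub <- new("RegionGenotypes", G = G, S = length(keep),
                 Rs = tcrossprod(G) / length(keep), ids = b@region@ids[keep],
                 positions = b@region@positions[keep], chrom = b@region@chrom)
      testRegion(des, sub, options = list(restarts = 2))@llr["iSetHet"]
    }, 0)
    which.max(het) == 3
  }, TRUE)
  expect_gt(mean(hits), 0.5)
})

test_that("single-variant interaction scan localizes a context-specific causal variant", {
  hits <- vapply(1:30, function(i) {
    geno <- simulateIndependentGenotypes(1000, mafs = runif(40, 0.1, 0.5),
                                         seed = 210 + i)
    rg <- standardizeRegion(geno)
    withr::with_seed(2100 + i, {
      causal <- sample(nVariants(rg), 1)
      g <- genotypes(rg)[, causal]
      Y <- cbind(sqrt(0.05) * g, 0) + matrix(rnorm(2000), 1000) * sqrt(0.95)
    })
    sc <- singleVariantInteractionScan(completeDesign(Y), rg,
                                       options = list(restarts = 1))
    sc$lead == causal
  }, TRUE)
  expect_gte(mean(hits), 0.9)
})

test_that("single-variant interaction p-values are uniform under persistent effects", {
  ps <- unlist(lapply(1:25, function(i) {
    geno <- simulateIndependentGenotypes(600, mafs = runif(80, 0.1, 0.5),
                                         seed = 240 + i)
    rg <- standardizeRegion(geno)
    b <- simulatePhenotypes(simulationConfig(seed = 2400 + i), rg)
    sc <- singleVariantInteractionScan(completeDesign(phenotypes(b)), rg,
                                       options = list(restarts = 1))
    sc$perVariant$interP
  }))
  expect_gt(length(ps), 1900)
  expect_gt(ks.test(ps, "punif")$p.value, 0.01)
})

test_that("region-level Bonferroni adjustment is exact", {
  geno <- simulateIndependentGenotypes(300, mafs = runif(30, 0.1, 0.5), seed = 7)
  rg <- standardizeRegion(geno)
  b <- simulatePhenotypes(simulationConfig(seed = 77), rg)
  sc <- singleVariantInteractionScan(completeDesign(phenotypes(b)), rg,
                                     adjust = "bonferroni",
                                     options = list(restarts = 1))
  expect_equal(sc$regionP,
               min(1, nVariants(rg) * min(sc$perVariant$interP, na.rm = TRUE)))
})

test_that("effective test count tracks the LD structure", {
  ortho <- tinyRegion(200, 10, seed = 50)
  expect_identical(effectiveTests(ortho), 10L)

  dup <- genotypes(ortho)
  dup[, 2] <- dup[, 1]
  rgDup <- new("RegionGenotypes", G = dup, S = 10L, Rs = tcrossprod(dup) / 10,
               ids = ortho@ids, positions = ortho@positions, chrom = "1")
  expect_lt(effectiveTests(rgDup), 10L)

  same <- dup; for (v in 1:10) same[, v] <- dup[, 1]
  rgSame <- new("RegionGenotypes", G = same, S = 10L, Rs = tcrossprod(same) / 10,
                ids = ortho@ids, positions = ortho@positions, chrom = "1")
  expect_identical(effectiveTests(rgSame), 1L)
})

test_that("baseline heterogeneity score follows the 1 - r2 rule", {
  expect_equal(heterogeneityBaselineScore(1e-5, 1e-4, r2 = 0), 1)
  expect_equal(heterogeneityBaselineScore(1e-5, 1e-4, r2 = 1), 0)
  expect_equal(heterogeneityBaselineScore(1e-5, 1e-4, r2 = 0.19), 0.81)
  expect_equal(heterogeneityBaselineScore(1e-5, 0.5, r2 = 0.19), 0)
  expect_equal(heterogeneityBaselineScore(NA, 1e-4, r2 = 0.19), 0)
})

test_that("architecture classification applies the LD interval rules", {
  expect_identical(classifyArchitecture(0.1, c(TRUE, TRUE))$class, "distinct-leads")
  sh <- classifyArchitecture(0.9, c(TRUE, TRUE), effectSigns = c(1, -1))
  expect_identical(sh$class, "shared-lead")
  expect_identical(sh$direction, "opposite")
  expect_identical(classifyArchitecture(0.9, c(TRUE, TRUE),
                                        effectSigns = c(1, 1))$direction, "same")
  expect_identical(classifyArchitecture(0.5, c(TRUE, TRUE))$class, "intermediate-LD")
  expect_identical(classifyArchitecture(0.1, c(TRUE, FALSE))$class, "unresolved")
  expect_identical(classifyArchitecture(NA, c(TRUE, TRUE))$class, "unresolved")
  expect_identical(classifyArchitecture(0.9, c(TRUE, TRUE), c(1, 1),
                                        secondarySignificant = c(TRUE, FALSE))$secondary,
                   "context-specific-secondary")
})

test_that("calibration is retained under model misspecification", {
  for (mode in c("single_causal", "epistasis")) {
    pv <- calibrationRun(60, J = 12, N = 500, seedBase = 31 + nchar(mode),
                         configFun = function(i)
                           simulationConfig(misspecification = mode,
                                            seed = 31000 + i),
                         tests = "iSet")
    band <- qbinom(c(0.005, 0.995), 60, 0.05) / 60
    expect_within(mean(pv$p_iSet <= 0.05), band[1], band[2],
                  label = paste("rejection rate under", mode))
  }
})
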