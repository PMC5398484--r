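test_that("variance decomposition attributes persistent-only signal to the persistent fraction", {
  fr <- vapply(1:25, function(i) {
    rg <- smallRegion(500, 50, seed = 300 + i)
    b <- simulatePhenotypes(simulationConfig(seed = 3000 + i), rg)
    decomposeVariance(completeDesign(phenotypes(b)), rg,
                      options = list(restarts = 2))$fractions
  }, numeric(5))
  expect_lt(mean(fr["rescaling", ]), 0.005)
  expect_lt(mean(fr["heterogeneity", ]), 0.005)
  expect_within(mean(fr["totalSet", ]), 0.01, 0.035)
})

test_that("negative rescaling leaves the persistent model without explained variance", {
  fr <- vapply(1:20, function(i) {
    rg <- smallRegion(500, 50, seed = 340 + i)
    b <- simulatePhenotypes(simulationConfig(architecture = "rescaling",
                                             proportionality = -1,
                                             regionVariance = 0.05,
                                             seed = 3400 + i), rg)
    decomposeVariance(completeDesign(phenotypes(b)), rg,
                      options = list(restarts = 2))$fractions
  }, numeric(5))
  expect_lt(mean(fr["persistent", ]), 0.005)
  expect_gt(mean(fr["rescaling", ]), 0.02)
})

test_that("decomposition fractions are invariant to trait scaling and sum consistently", {
  rg <- smallRegion(400, 40, seed = 370)
  b <- simulatePhenotypes(simulationConfig(architecture = "rescaling",
                                           proportionality = 0.5,
                                           regionVariance = 0.08, seed = 370), rg)
  d1 <- decomposeVariance(completeDesign(phenotypes(b)), rg)
  d2 <- decomposeVariance(completeDesign(3 * phenotypes(b)), rg)
  expect_equal(d1$fractions, d2$fractions, tolerance = 1e-3)
  f <- d1$fractions
  expect_equal(unname(f["persistent"] + f["rescaling"] + f["heterogeneity"]),
               unname(f["totalSet"]), tolerance = 1e-10)
  expect_true(all(f >= 0))
  # explained set variance along the nested hierarchy: the REML fits are
  # nested in likelihood, and the diagonal-based explained variance tracks
  # that ordering up to small attribution differences between structures
  expect_true(all(diff(d1$explained) >= -0.01))
})

test_that("BLUP has its closed forms and shrinks toward zero", {
  y <- c(1, -2, 3, 0.5)
  expect_equal(blupCis(y, diag(4), sigma2cis = 0, V = diag(4)), rep(0, 4))
  expect_equal(blupCis(y, diag(4), sigma2cis = 1, V = 2 * diag(4)), y / 2)
  expect_error(blupCis(y, diag(4), 1, matrix(0, 4, 4)), "singular")
  withr::with_seed(5, {
    K <- tcrossprod(matrix(rnorm(40), 8)) / 5
    V <- K + diag(8)
    yy <- rnorm(8)
    pred <- blupCis(yy, K, 0.7, V, mu = mean(yy))
    M <- 0.7 * K %*% solve(V)
    bound <- norm(M, "2") * sqrt(sum((yy - mean(yy))^2))
    expect_lte(sqrt(sum(pred^2)), bound + 1e-10)
  })
})

test_that("cross-context BLUP correlation is lower under heterogeneity than persistence", {
  blupCor <- function(arch, i) {
    rg <- smallRegion(400, 40, seed = 400 + i)
    b <- simulatePhenotypes(simulationConfig(architecture = arch, nCausal = 2,
                                             targetCorr = 0,
                                             regionVariance = 0.1,
                                             seed = 4000 + i), rg)
    Y <- phenotypes(b)
    f1 <- fitSingleContext(Y[, 1], rg, options = list(restarts = 2))
    f2 <- fitSingleContext(Y[, 2], rg, options = list(restarts = 2))
    cor(f1$blup, f2$blup)
  }
  cP <- vapply(1:12, function(i) blupCor("persistent", i), 0)
  cH <- vapply(1:12, function(i) blupCor("heterogeneity", i + 50), 0)
  expect_gt(mean(cP), mean(cH))
})

test_that("enrichment odds ratio and exact p behave on printed and analytic tables", {
  e <- enrichmentOddsRatio(rbind(c(8, 59), c(238, 3881)))
  expect_equal(round(e$oddsRatio, 1), 2.2)
  expect_lt(e$pValue, 5e-2)

  flat <- enrichmentOddsRatio(rbind(c(1, 1), c(1, 1)))
  expect_equal(flat$oddsRatio, 1)
  expect_gt(flat$pValue, 0.5)

  ext <- enrichmentOddsRatio(rbind(c(5, 0), c(0, 5)))
  expect_true(ext$infinite)
  expect_equal(ext$pValue, 1 / choose(10, 5))
})
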