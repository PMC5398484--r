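test_that("variance ledger is exact per context and sums to one", {
  rg <- smallRegion(300, 60, seed = 31)
  b <- simulatePhenotypes(simulationConfig(seed = 7), rg)
  led <- varianceLedger(b)
  for (cc in 1:2) {
    tot <- sum(vapply(led, `[`, 0, cc))
    expect_equal(tot, 1, tolerance = 1e-10)
    expect_equal(var(b@components$structure[, cc]), led$structure[cc],
                 tolerance = 1e-10)
    expect_equal(var(b@components$hidden[, cc]), led$hidden[cc],
                 tolerance = 1e-10)
    expect_equal(var(b@components$noise[, cc]), led$noise[cc],
                 tolerance = 1e-10)
    expect_equal(var(b@components$region[, cc]), led$region[cc],
                 tolerance = 1e-10)
  }
  # defaults: persistent architecture hits v_r exactly in both contexts
  expect_equal(unname(led$region), c(0.02, 0.02), tolerance = 1e-10)
})

test_that("architecture identities hold on W", {
  rg <- smallRegion(300, 60, seed = 31)
  p <- simulatePhenotypes(simulationConfig(architecture = "persistent",
                                           seed = 3), rg)
  expect_equal(trueEffects(p)[, 1], trueEffects(p)[, 2])

  r <- simulatePhenotypes(simulationConfig(architecture = "rescaling",
                                           proportionality = -0.5, seed = 4), rg)
  expect_equal(trueEffects(r)[, 2], -0.5 * trueEffects(r)[, 1], tolerance = 1e-12)

  # eta = 1 corresponds to no interaction: regional effects equal across contexts
  r1 <- simulatePhenotypes(simulationConfig(architecture = "rescaling",
                                            proportionality = 1, seed = 5), rg)
  expect_equal(trueEffects(r1)[, 1], trueEffects(r1)[, 2])
  expect_equal(r1@components$region[, 1], r1@components$region[, 2])
})

test_that("heterogeneity mode hits the target effect correlation", {
  rg <- smallRegion(400, 60, seed = 32)
  for (tc in c(0, 0.5)) {
    b <- simulatePhenotypes(simulationConfig(architecture = "heterogeneity",
                                             nCausal = 2, targetCorr = tc,
                                             seed = 60 + round(10 * tc)), rg)
    r <- cor(b@components$region[, 1], b@components$region[, 2])
    expect_within(r, tc - 0.05, tc + 0.05)
    expect_equal(unname(vapply(b@components["region"], function(m)
      var(m[, 1]), 0)), 0.02, tolerance = 1e-10)
  }
  expect_error(
    simulatePhenotypes(simulationConfig(architecture = "heterogeneity",
                                        nCausal = 2, targetCorr = 1,
                                        corrTol = 1e-6, seed = 1), rg),
    "unreachable target correlation")
})

test_that("background (structure + hidden) components are correlated ~alpha across contexts", {
  rg <- smallRegion(150, 40, seed = 33)
  rr <- vapply(1:200, function(i) {
    b <- simulatePhenotypes(simulationConfig(seed = 4000 + i), rg)
    bg <- b@components$structure + b@components$hidden
    cor(bg[, 1], bg[, 2])
  }, 0)
  expect_within(mean(rr), 0.55, 0.65)
})

test_that("misspecification modes behave as specified", {
  rg <- smallRegion(2000, 60, seed = 34)
  b <- simulatePhenotypes(simulationConfig(seed = 8), rg)

  sc <- applyMisspecification(b, "single_causal", seed = 2)
  expect_identical(sum(rowSums(abs(trueEffects(sc))) > 0), 1L)

  ep <- applyMisspecification(b, "epistasis", seed = 3)
  expect_equal(ep@Y - ep@components$epistasis, b@Y, tolerance = 1e-12)

  # outliers: expected count 0.1% of N*C entries; offsets exactly +-8
  nPert <- vapply(1:60, function(i) {
    o <- applyMisspecification(b, "outliers", seed = 100 + i)
    pert <- o@Y - b@Y
    expect_true(all(abs(abs(pert[pert != 0]) - 8) < 1e-9))
    sum(pert != 0)
  }, 0)
  expect_within(mean(nPert), 4 * 0.7, 4 * 1.3)   # Binomial(4000, 0.001)
})

test_that("stratification is a fair Bernoulli split, deterministic by seed", {
  rg <- smallRegion(2000, 60, seed = 34)
  b <- simulatePhenotypes(simulationConfig(seed = 8), rg)
  d1 <- stratifyBundle(b, seed = 5)
  d2 <- stratifyBundle(b, seed = 5)
  expect_identical(d1@context, d2@context)
  expect_identical(length(d1@y), 2000L)
  n1 <- sum(d1@context == 1L)
  band <- qbinom(c(5e-4, 1 - 5e-4), 2000, 0.5)
  expect_within(n1, band[1], band[2])
  expect_equal(d1@y, b@Y[cbind(seq_len(2000), d1@context)])
})

test_that("illustration region has three disjoint 5% loci", {
  b <- simulateIllustrationRegion(seed = 2, nIndividuals = 300)
  fr <- varianceLedger(b)
  for (k in 1:3)
    expect_equal(unname(fr[[paste0("locus", k)]]),
                 rep(mean(apply(b@components[[paste0("locus", k)]], 2, var)), 2),
                 tolerance = 1e-10)
  # mean per-context fraction of each locus is 5% of unit total variance
  for (k in 1:3)
    expect_equal(mean(apply(b@components[[paste0("locus", k)]], 2, var)), 0.05,
                 tolerance = 1e-10)
  ci <- b@causalIndices
  sets <- lapply(ci, function(x) sort(unique(unlist(x))))
  expect_length(intersect(sets$persistent, sets$rescaling), 0)
  expect_length(intersect(sets$persistent, sets$heterogeneity), 0)
  expect_length(intersect(sets$rescaling, sets$heterogeneity), 0)
  # persistent locus: identical W columns on its causal variants
  idx <- sets$persistent
  expect_equal(trueEffects(b)[idx, 1], trueEffects(b)[idx, 2])
})

test_that("phenotype and truth TSV exports are readable", {
  rg <- smallRegion(300, 60, seed = 31)
  b <- simulatePhenotypes(simulationConfig(seed = 7), rg)
  f <- withr::local_tempfile(fileext = ".tsv")
  writePhenotypeTSV(b, f)
  Y <- readPhenotypes(f, "complete")
  expect_equal(unname(Y), unname(b@Y))
  ft <- withr::local_tempfile(fileext = ".tsv")
  writeTruthTSV(b, ft)
  tr <- read.table(ft, header = TRUE, sep = "\t")
  expect_identical(nrow(tr), 2L * nVariants(rg))
})
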