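# Phenotype simulation across contexts: regional genetic effects with
# persistent / rescaling / heterogeneity architectures, structured
# confounding (population structure + hidden factors, correlated across
# contexts), iid noise, and misspecification modes for calibration checks.
#
# Per context the variance budget is: region v_r; of the residual 1 - v_r,
# a fraction beta comes from hidden factors, a fraction structureFraction
# of the remainder from population structure, and the rest is iid noise.
# The region component is rescaled by a single factor shared across contexts
# (so rescaling architectures keep their fold change of explained variance),
# targeting a mean per-context fraction of v_r; the remaining components are
# rescaled per context so each context's ledger sums exactly to one.

#' Simulate phenotypes across contexts from regional genetic effects
#'
#' @param config a \linkS4class{SimulationConfig}.
#' @param region a \linkS4class{RegionGenotypes} carrying the causal region.
#' @param background optional \linkS4class{DosageMatrix} (or relatedness
#'   matrix) from which the population-structure component is drawn; when
#'   NULL the structure component has no genetic covariance (homogeneous
#'   cohort) and acts as an additional shared confounder.
#' @return A \linkS4class{PhenotypeBundle}.
#' @export
simulatePhenotypes <- function(config, region, background = NULL) {
  stopifnot(is(config, "SimulationConfig"), is(region, "RegionGenotypes"))
  validObject(config)
  cfg <- config
  if (config@misspecification == "single_causal") cfg@nCausal <- 1L
  bundle <- withSeed(config@seed, .simulateBundle(cfg, region, background))
  bundle@config <- config
  if (config@misspecification %in% c("epistasis", "outliers"))
    bundle <- applyMisspecification(bundle, config@misspecification,
                                    childSeed(config@seed, 99L))
  bundle
}

.simulateBundle <- function(config, region, background) {
  C <- config@nContexts
  N <- nrow(region@G)
  S <- region@S
  nc <- config@nCausal
  need <- if (config@architecture == "heterogeneity") 2L * nc else nc
  if (S < need)
    stop(sprintf("region has %d variants; architecture needs >= %d", S, need))

  arch <- .drawArchitecture(config, region)
  W <- arch$W
  regionRaw <- region@G %*% W                       # N x C

  # Scaling policy: persistent and rescaling architectures use one factor
  # shared across contexts (preserving the fold change of explained
  # variance implied by the proportionality factor), targeting a mean
  # per-context fraction of v_r.  The heterogeneity architecture scales
  # each context's effect column to exactly v_r (column scaling leaves the
  # effect correlation untouched), matching equal per-context explained
  # variance while the causal configuration differs.
  regionC <- matrix(0, N, C)
  if (config@regionVariance > 0) {
    if (config@architecture == "heterogeneity") {
      for (cc in seq_len(C)) {
        vc <- stats::var(regionRaw[, cc])
        if (vc > 1e-300) {
          sc <- sqrt(config@regionVariance / vc)
          W[, cc] <- W[, cc] * sc
          regionC[, cc] <- regionRaw[, cc] * sc
        }
      }
    } else {
      vbar <- mean(apply(regionRaw, 2, stats::var))
      if (vbar > 1e-300) {
        sc <- sqrt(config@regionVariance / vbar)
        W <- W * sc
        regionC <- regionRaw * sc
      }
    }
  }
  fRegion <- apply(regionC, 2, stats::var)

  Lr <- .structureFactor(background, N)
  alpha <- config@sharedBackground
  z0 <- rnorm(N)
  structC <- vapply(seq_len(C), function(cc)
    as.numeric(Lr %*% (sqrt(alpha) * z0 + sqrt(1 - alpha) * rnorm(N))),
    numeric(N))

  Kh <- config@nHidden
  Zf <- matrix(rnorm(N * Kh), N, Kh)
  l0 <- rnorm(Kh)
  hiddenC <- vapply(seq_len(C), function(cc)
    as.numeric(Zf %*% (sqrt(alpha) * l0 + sqrt(1 - alpha) * rnorm(Kh))),
    numeric(N))

  noiseC <- matrix(rnorm(N * C), N, C)

  fracs <- matrix(0, 4, C,
                  dimnames = list(c("region", "structure", "hidden", "noise"), NULL))
  fracs["region", ] <- fRegion
  for (cc in seq_len(C)) {
    res <- max(1 - fRegion[cc], 0)
    vh <- config@hiddenFraction * res
    vs <- config@structureFraction * (1 - config@hiddenFraction) * res
    vn <- res - vh - vs
    structC[, cc] <- scaleToVar(structC[, cc], vs)
    hiddenC[, cc] <- scaleToVar(hiddenC[, cc], vh)
    noiseC[, cc] <- scaleToVar(noiseC[, cc], vn)
    fracs["structure", cc] <- vs
    fracs["hidden", cc] <- vh
    fracs["noise", cc] <- vn
  }

  Y <- regionC + structC + hiddenC + noiseC
  new("PhenotypeBundle", Y = Y,
      components = list(region = regionC, structure = structC,
                        hidden = hiddenC, noise = noiseC),
      fractions = list(region = fracs["region", ],
                       structure = fracs["structure", ],
                       hidden = fracs["hidden", ],
                       noise = fracs["noise", ]),
      W = W, causalIndices = arch$causal, config = config, region = region)
}

.structureFactor <- function(background, N) {
  if (is.null(background)) return(diag(N))
  R <- if (is(background, "DosageMatrix")) {
    G <- .standardizeDosages(background@dosages)
    tcrossprod(G) / ncol(G)
  } else as.matrix(background)
  stopifnot(nrow(R) == N)
  t(chol(R + diag(1e-6, N)))
}

.drawArchitecture <- function(config, region) {
  S <- region@S
  nc <- config@nCausal
  C <- config@nContexts
  W <- matrix(0, S, C)
  if (config@architecture == "persistent") {
    idx <- sample.int(S, nc)
    eff <- rnorm(nc)
    for (cc in seq_len(C)) W[idx, cc] <- eff
    list(W = W, causal = rep(list(sort(idx)), C))
  } else if (config@architecture == "rescaling") {
    stopifnot(C == 2L)
    idx <- sample.int(S, nc)
    eff <- rnorm(nc)
    W[idx, 1] <- eff
    W[idx, 2] <- config@proportionality * eff
    list(W = W, causal = rep(list(sort(idx)), 2))
  } else {
    stopifnot(C == 2L)
    G <- region@G
    band <- if (length(config@corrBand) == 2) config@corrBand
            else config@targetCorr + c(-1, 1) * config@corrTol
    for (attempt in seq_len(10000L)) {
      i1 <- sample.int(S, nc)
      i2 <- sample.int(S, nc)
      Wt <- matrix(0, S, 2)
      Wt[i1, 1] <- rnorm(nc)
      Wt[i2, 2] <- Wt[i2, 2] + rnorm(nc)
      g <- G %*% Wt
      r <- stats::cor(g[, 1], g[, 2])
      if (is.finite(r) && r >= band[1] && r <= band[2])
        return(list(W = Wt, causal = list(sort(i1), sort(i2))))
    }
    stop("unreachable target correlation: rejection sampling exhausted")
  }
}

#' Apply a model-misspecification mode to a simulated bundle
#'
#' \code{single_causal} regenerates the regional component with a single
#' causal variant; \code{epistasis} adds the product of a random variant
#' pair to the genetic component (persistently, in both contexts);
#' \code{outliers} adds offsets of +-8 to a random 0.1\% of trait entries.
#'
#' @param bundle a \linkS4class{PhenotypeBundle}.
#' @param mode "single_causal", "epistasis" or "outliers".
#' @param seed RNG seed.
#' @return a modified \linkS4class{PhenotypeBundle}.
#' @export
applyMisspecification <- function(bundle, mode = c("single_causal", "epistasis",
                                                   "outliers"), seed = 1L) {
  mode <- match.arg(mode)
  config <- bundle@config
  if (mode == "single_causal") {
    cfg <- config
    cfg@nCausal <- 1L
    cfg@misspecification <- "none"
    cfg@seed <- as.integer(seed)
    out <- withSeed(seed, .simulateBundle(cfg, bundle@region, NULL))
    out@config@misspecification <- "single_causal"
    return(out)
  }
  N <- nrow(bundle@Y)
  C <- ncol(bundle@Y)
  if (mode == "epistasis") {
    S <- bundle@region@S
    if (S < 2) stop("epistasis mode needs at least 2 variants")
    withSeed(seed, {
      pair <- sample.int(S, 2)
      term <- bundle@region@G[, pair[1]] * bundle@region@G[, pair[2]]
      term <- scaleToVar(term, config@regionVariance)
      epi <- matrix(term, N, C)
      bundle@components$epistasis <- epi
      bundle@Y <- bundle@Y + epi
      bundle@config@misspecification <- "epistasis"
      bundle
    })
  } else {
    withSeed(seed, {
      hit <- which(matrix(stats::runif(N * C) < 0.001, N, C))
      if (length(hit)) {
        offs <- 8 * sample(c(-1, 1), length(hit), replace = TRUE)
        pert <- matrix(0, N, C)
        pert[hit] <- offs
        bundle@components$outliers <- pert
        bundle@Y <- bundle@Y + pert
      }
      bundle@config@misspecification <- "outliers"
      bundle
    })
  }
}

#' Stratify a complete-design bundle into a one-context-per-individual design
#'
#' Each individual is assigned one observed context by an independent fair
#' Bernoulli draw; the returned design contains the single observed trait
#' value and the context label per individual.
#'
#' @param bundle a two-context \linkS4class{PhenotypeBundle}.
#' @param seed RNG seed.
#' @param F fixed-effect covariates for the returned design (default
#'   intercept).
#' @return a stratified \linkS4class{StudyDesign}.
#' @export
stratifyBundle <- function(bundle, seed = 1L, F = NULL) {
  stopifnot(ncol(bundle@Y) == 2L)
  N <- nrow(bundle@Y)
  withSeed(seed, {
    ctx <- 1L + stats::rbinom(N, 1L, 0.5)
    y <- bundle@Y[cbind(seq_len(N), ctx)]
    stratifiedDesign(y, ctx, F %||% matrix(1, N, 1), C = 2L)
  })
}

#' Simulate the multi-locus illustration region
#'
#' A mosaic cohort over a long region containing three disjoint 30-kb causal
#' loci with persistent, rescaling and heterogeneity architectures; each
#' locus component is rescaled (common factor across the two contexts) so
#' its mean per-context variance fraction is 5\% of the total phenotypic
#' variance.
#'
#' @param seed RNG seed.
#' @param nIndividuals cohort size.
#' @param nCausal causal variants per locus (per context for the
#'   heterogeneity locus).
#' @return A \linkS4class{PhenotypeBundle} whose components include
#'   locusPersistent, locusRescaling and locusHeterogeneity, with the locus
#'   windows in the "loci" attribute of the components list.
#' @export
simulateIllustrationRegion <- function(seed = 1L, nIndividuals = 500L,
                                       nCausal = 2L) {
  # three 30-kb causal loci far apart within a long region, so inter-locus
  # LD is negligible: each locus is an independent mosaic draw
  lociStart <- c(0, 2400000, 4800000)
  lociEnd <- lociStart + 30000
  parts <- lapply(1:3, function(k)
    simulateMosaicCohort(nIndividuals, nVariants = 150L,
                         regionLengthBp = 30000L,
                         seed = childSeed(seed, 1L, k),
                         startBp = lociStart[k]))
  dosAll <- do.call(cbind, lapply(parts, dosages))
  posAll <- unlist(lapply(parts, positions))
  region <- standardizeRegion(DosageMatrix(dosAll, posAll,
                                           chrom = parts[[1]]@chrom),
                              mafMin = 0.02)
  N <- nIndividuals
  vLocus <- 0.05
  withSeed(childSeed(seed, 2L), {
    comps <- list()
    Wall <- matrix(0, region@S, 2)
    causal <- list()
    archs <- c("persistent", "rescaling", "heterogeneity")
    for (k in 1:3) {
      inLocus <- which(region@positions >= lociStart[k] &
                       region@positions < lociEnd[k])
      sub <- new("RegionGenotypes",
                 G = region@G[, inLocus, drop = FALSE],
                 S = length(inLocus),
                 Rs = tcrossprod(region@G[, inLocus, drop = FALSE]) / length(inLocus),
                 ids = region@ids[inLocus],
                 positions = region@positions[inLocus], chrom = region@chrom)
      cfg <- simulationConfig(architecture = archs[k], nCausal = nCausal,
                              proportionality = -0.5, targetCorr = 0,
                              seed = childSeed(seed, 10L + k))
      arch <- .drawArchitecture(cfg, sub)
      g <- sub@G %*% arch$W
      W <- arch$W
      if (archs[k] == "heterogeneity") {
        for (cc in 1:2) {
          sc <- sqrt(vLocus / stats::var(g[, cc]))
          W[, cc] <- W[, cc] * sc
          g[, cc] <- g[, cc] * sc
        }
      } else {
        sc <- sqrt(vLocus / mean(apply(g, 2, stats::var)))
        W <- W * sc
        g <- g * sc
      }
      comps[[paste0("locus", k)]] <- g
      Wall[inLocus, ] <- Wall[inLocus, ] + W
      causal[[k]] <- lapply(arch$causal, function(ii) inLocus[ii])
    }
    gTot <- Reduce(`+`, comps)
    fLoci <- vapply(comps, function(m) mean(apply(m, 2, stats::var)), 0)
    lv <- vapply(comps, function(m) apply(m, 2, stats::var), numeric(2))
    res <- pmax(1 - rowSums(lv), 0)
    alpha <- 0.6
    z0 <- rnorm(N)
    hiddenC <- noiseC <- matrix(0, N, 2)
    Zf <- matrix(rnorm(N * 10), N, 10)
    l0 <- rnorm(10)
    fr <- list()
    for (cc in 1:2) {
      vh <- 0.5 * res[cc]
      vn <- res[cc] - vh
      hiddenC[, cc] <- scaleToVar(as.numeric(Zf %*% (sqrt(alpha) * l0 +
                                   sqrt(1 - alpha) * rnorm(10))), vh)
      noiseC[, cc] <- scaleToVar(rnorm(N), vn)
    }
    Y <- gTot + hiddenC + noiseC
    comps$hidden <- hiddenC
    comps$noise <- noiseC
    attr(comps, "loci") <- data.frame(start = lociStart, end = lociEnd,
                                      architecture = archs)
    cfg0 <- simulationConfig(seed = as.integer(seed))
    new("PhenotypeBundle", Y = Y, components = comps,
        fractions = list(locus1 = rep(fLoci[1], 2), locus2 = rep(fLoci[2], 2),
                         locus3 = rep(fLoci[3], 2)),
        W = Wall,
        causalIndices = list(persistent = causal[[1]], rescaling = causal[[2]],
                             heterogeneity = causal[[3]]),
        config = cfg0, region = region)
  })
}

# ---------------------------------------------------------------------------
# fixture export
# ---------------------------------------------------------------------------

#' Write bundle phenotypes as a long-format TSV
#'
#' Columns: sample_id, context, value.
#'
#' @param bundle a \linkS4class{PhenotypeBundle} (or StudyDesign).
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writePhenotypeTSV <- function(bundle, path) {
  if (is(bundle, "PhenotypeBundle")) {
    Y <- bundle@Y
    df <- data.frame(sample_id = rep(paste0("S", seq_len(nrow(Y))), ncol(Y)),
                     context = rep(seq_len(ncol(Y)), each = nrow(Y)),
                     value = as.vector(Y))
  } else if (is(bundle, "StudyDesign") && bundle@layout == "stratified") {
    df <- data.frame(sample_id = paste0("S", seq_along(bundle@y)),
                     context = bundle@context, value = bundle@y)
  } else if (is(bundle, "StudyDesign")) {
    Y <- bundle@Y
    df <- data.frame(sample_id = rep(paste0("S", seq_len(nrow(Y))), ncol(Y)),
                     context = rep(seq_len(ncol(Y)), each = nrow(Y)),
                     value = as.vector(Y))
  } else stop("unsupported object")
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write true variant effects as a TSV
#'
#' Columns: variant, context, effect.
#'
#' @param bundle a \linkS4class{PhenotypeBundle}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeTruthTSV <- function(bundle, path) {
  W <- bundle@W
  df <- data.frame(variant = rep(bundle@region@ids, ncol(W)),
                   context = rep(seq_len(ncol(W)), each = nrow(W)),
                   effect = as.vector(W))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
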