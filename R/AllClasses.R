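#' @include utils.R
NULL

# ---------------------------------------------------------------------------
# DosageMatrix: raw diploid allele counts for a genomic region or cohort
# ---------------------------------------------------------------------------

#' DosageMatrix: diploid allele dosages
#'
#' Container for raw variant dosages (alternate-allele counts in 0/1/2) for a
#' set of individuals, with base-pair positions (0-based half-open
#' convention), a chromosome label, per-variant alternate-allele frequencies
#' and optional subpopulation labels.
#'
#' @slot dosages integer-valued matrix, individuals x variants, entries in
#'   \{0, 1, 2\} (NA permitted for missing genotypes read from files).
#' @slot positions integer vector of strictly increasing 0-based positions.
#' @slot chrom chromosome label.
#' @slot alleleFreqs empirical alternate-allele fraction per variant.
#' @slot groups optional integer subpopulation label per individual
#'   (length 0 when absent).
#' @exportClass DosageMatrix
setClass("DosageMatrix",
         representation(dosages = "matrix", positions = "numeric",
                        chrom = "character", alleleFreqs = "numeric",
                        groups = "integer"),
         prototype(groups = integer(0)))

setValidity("DosageMatrix", function(object) {
  d <- object@dosages
  msg <- character(0)
  if (ncol(d) != length(object@positions))
    msg <- c(msg, "positions length must match number of variants")
  if (ncol(d) != length(object@alleleFreqs))
    msg <- c(msg, "alleleFreqs length must match number of variants")
  if (length(object@positions) > 1 && any(diff(object@positions) <= 0))
    msg <- c(msg, "positions must be strictly increasing")
  ok <- d[!is.na(d)]
  if (length(ok) && (min(ok) < 0 || max(ok) > 2))
    msg <- c(msg, "dosages must lie in {0, 1, 2}")
  if (length(object@groups) && length(object@groups) != nrow(d))
    msg <- c(msg, "groups length must match number of individuals")
  if (length(msg)) msg else TRUE
})

DosageMatrix <- function(dosages, positions, chrom = "1",
                         alleleFreqs = colMeans(dosages, na.rm = TRUE) / 2,
                         groups = integer(0)) {
  new("DosageMatrix", dosages = dosages, positions = as.numeric(positions),
      chrom = chrom, alleleFreqs = as.numeric(alleleFreqs),
      groups = as.integer(groups))
}

# ---------------------------------------------------------------------------
# RegionGenotypes: standardized dosages and the local relatedness kernel
# ---------------------------------------------------------------------------

#' RegionGenotypes: standardized region genotypes
#'
#' Standardized variant dosages G (per-variant mean 0, variance 1) for a
#' testing region, with the derived local realized relatedness matrix
#' Rs = G G' / S used as the kernel of the set component.
#'
#' @slot G numeric matrix, individuals x variants, standardized dosages.
#' @slot S integer variant count.
#' @slot Rs individuals x individuals local realized relatedness matrix.
#' @slot ids variant identifiers.
#' @slot positions 0-based variant positions.
#' @slot chrom chromosome label.
#' @exportClass RegionGenotypes
setClass("RegionGenotypes",
         representation(G = "matrix", S = "integer", Rs = "matrix",
                        ids = "character", positions = "numeric",
                        chrom = "character"))

setValidity("RegionGenotypes", function(object) {
  msg <- character(0)
  if (ncol(object@G) != object@S)
    msg <- c(msg, "S must equal ncol(G)")
  if (nrow(object@Rs) != nrow(object@G) || ncol(object@Rs) != nrow(object@G))
    msg <- c(msg, "Rs must be square with dim equal to nrow(G)")
  if (abs(mean(diag(object@Rs)) - 1) > 1e-6)
    msg <- c(msg, "mean diagonal of Rs must be 1")
  if (length(msg)) msg else TRUE
})

# ---------------------------------------------------------------------------
# StudyDesign: phenotypes plus fixed-effect covariates
# ---------------------------------------------------------------------------

#' StudyDesign: phenotype layout and fixed-effect covariates
#'
#' A complete design holds an N x C trait matrix (every individual phenotyped
#' in all C contexts); a stratified design holds one observed trait value and
#' one context label per individual.  Fixed-effect covariates F (including an
#' intercept and, typically, genotype principal components) are shared.
#'
#' @slot layout "complete" or "stratified".
#' @slot Y N x C trait matrix (complete layout; 0-column otherwise).
#' @slot y length-N observed trait vector (stratified layout).
#' @slot context integer context label in 1..C per individual (stratified).
#' @slot F N x K fixed-effect covariate matrix (full column rank).
#' @slot C integer context count.
#' @exportClass StudyDesign
setClass("StudyDesign",
         representation(layout = "character", Y = "matrix", y = "numeric",
                        context = "integer", F = "matrix", nContexts = "integer"))

setValidity("StudyDesign", function(object) {
  msg <- character(0)
  N <- designN(object)
  if (!object@layout %in% c("complete", "stratified"))
    msg <- c(msg, "layout must be 'complete' or 'stratified'")
  if (object@layout == "complete") {
    if (ncol(object@Y) != object@nContexts) msg <- c(msg, "ncol(Y) must equal C")
    if (anyNA(object@Y)) msg <- c(msg, "Y must not contain missing values")
  } else {
    if (length(object@y) != length(object@context))
      msg <- c(msg, "y and context must have equal length")
    if (anyNA(object@y)) msg <- c(msg, "y must not contain missing values")
    if (length(object@context) &&
        (min(object@context) < 1L || max(object@context) > object@nContexts))
      msg <- c(msg, "context labels must lie in 1..C")
    if (any(tabulate(object@context, object@nContexts) < 2L))
      msg <- c(msg, "every context must be represented by at least 2 individuals")
  }
  if (ncol(object@F) > 0) {
    if (nrow(object@F) != N) msg <- c(msg, "nrow(F) must equal N")
    if (qr(object@F)$rank < ncol(object@F))
      msg <- c(msg, "F must have full column rank")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a complete (repeat-measurement) study design
#'
#' @param Y N x C matrix of trait values, one column per context.
#' @param F N x K fixed-effect covariate matrix; defaults to an intercept.
#' @return A \linkS4class{StudyDesign} with layout "complete".
#' @export
completeDesign <- function(Y, F = matrix(1, nrow(Y), 1)) {
  Y <- as.matrix(Y)
  new("StudyDesign", layout = "complete", Y = Y, y = numeric(0),
      context = integer(0), F = as.matrix(F), nContexts = ncol(Y))
}

#' Construct a stratified study design
#'
#' Each individual is phenotyped in exactly one context (e.g. males versus
#' females in a sex-stratified analysis).
#'
#' @param y length-N vector of observed trait values.
#' @param context integer context label in 1..C per individual.
#' @param F N x K fixed-effect covariate matrix; defaults to an intercept.
#' @param C number of contexts.
#' @return A \linkS4class{StudyDesign} with layout "stratified".
#' @export
stratifiedDesign <- function(y, context, F = matrix(1, length(y), 1),
                             C = max(context)) {
  new("StudyDesign", layout = "stratified", Y = matrix(0, 0, 0),
      y = as.numeric(y), context = as.integer(context),
      F = as.matrix(F), nContexts = as.integer(C))
}

designN <- function(design) {
  if (design@layout == "complete") nrow(design@Y) else length(design@y)
}

# ---------------------------------------------------------------------------
# TraitContextCovariance
# ---------------------------------------------------------------------------

#' TraitContextCovariance: structured C x C covariance
#'
#' Parametrization of the trait-context covariance of the set component.
#' The structural kinds map one-to-one onto genetic architectures:
#' "null" (no set effect), "block" (persistent effects, a0 * ones),
#' "rank1" (rescaling interactions, a a'), "full" (heterogeneity, A A' with
#' A lower triangular).  All kinds are positive semidefinite by construction
#' for any value of the free parameters.
#'
#' @slot kind one of "null", "block", "rank1", "full".
#' @slot theta free parameter vector (length 0, 1, C, C(C+1)/2).
#' @slot C context count.
#' @exportClass TraitContextCovariance
setClass("TraitContextCovariance",
         representation(kind = "character", theta = "numeric", nContexts = "integer"))

setValidity("TraitContextCovariance", function(object) {
  if (!object@kind %in% covKinds) return("unknown kind")
  if (length(object@theta) != nParS(object@kind, object@nContexts))
    return(sprintf("theta must have length %d for kind '%s' with C = %d",
                   nParS(object@kind, object@nContexts), object@kind, object@nContexts))
  TRUE
})

#' Construct a structured trait-context covariance
#'
#' @param kind covariance structure: "null", "block", "rank1" or "full".
#' @param theta free parameters (none, a scalar, a length-C vector, or the
#'   C(C+1)/2 entries of a lower-triangular factor, column-major).
#' @param C context count.
#' @return A \linkS4class{TraitContextCovariance}.
#' @export
traitContextCovariance <- function(kind, theta = numeric(0), C = 2L) {
  new("TraitContextCovariance", kind = match.arg(kind, covKinds),
      theta = as.numeric(theta), nContexts = as.integer(C))
}

#' Materialize a structured covariance as a dense matrix
#'
#' @param cov A \linkS4class{TraitContextCovariance}.
#' @return The C x C covariance matrix (always positive semidefinite).
#' @export
materializeCovariance <- function(cov) {
  stopifnot(is(cov, "TraitContextCovariance"))
  validObject(cov)
  csFromTheta(cov@theta, cov@kind, cov@nContexts)
}

# ---------------------------------------------------------------------------
# FittedModel
# ---------------------------------------------------------------------------

#' FittedModel: a fitted interaction set LMM
#'
#' @slot kind structure of the fitted trait-context covariance Cs.
#' @slot layout design layout the model was fitted to.
#' @slot Cs fitted C x C set covariance.
#' @slot Cn fitted C x C residual covariance (diagonal for stratified fits).
#' @slot B fitted K x C fixed-effect matrix.
#' @slot thetaS,thetaN parameter vectors at the optimum.
#' @slot logLik restricted log-likelihood at the optimum.
#' @slot converged TRUE when at least one restart converged.
#' @slot nEvals total objective evaluations across restarts.
#' @slot restart index of the restart that attained the optimum.
#' @exportClass FittedModel
setClass("FittedModel",
         representation(kind = "character", layout = "character",
                        Cs = "matrix", Cn = "matrix", B = "matrix",
                        thetaS = "numeric", thetaN = "numeric",
                        logLik = "numeric", converged = "logical",
                        nEvals = "integer", restart = "integer"))

# ---------------------------------------------------------------------------
# SimulationConfig
# ---------------------------------------------------------------------------

#' SimulationConfig: generative settings for two-context phenotypes
#'
#' Phenotypes are simulated per context as the sum of a regional (set)
#' genetic component, a population-structure component, effects of hidden
#' confounding factors, and iid Gaussian noise.  Defaults correspond to the
#' standard study conditions: region variance fraction 2\%, background
#' (structure + hidden) correlated across contexts with coefficient 0.6,
#' hidden factors explaining half of the residual variance via K = 10
#' factors.
#'
#' @slot nContexts number of contexts C (default 2).
#' @slot regionVariance v_r: fraction of per-context phenotypic variance
#'   from the variant set (default 0.02).
#' @slot sharedBackground alpha: cross-context correlation of the structured
#'   background (structure and hidden components; default 0.6).
#' @slot hiddenFraction beta: fraction of the residual (non-region) variance
#'   from hidden factors (default 0.5).
#' @slot structureFraction fraction of the non-hidden residual attributed to
#'   population structure (default 0.2; see the methods vignette).
#' @slot nHidden number of hidden factors K (default 10).
#' @slot architecture "persistent", "rescaling" or "heterogeneity".
#' @slot nCausal causal variants (per context for heterogeneity; default 4).
#' @slot proportionality eta in [-1, 1]: rescaling factor of effect sizes
#'   between the two contexts (rescaling architecture).
#' @slot targetCorr r in [-1, 1]: target correlation of the total regional
#'   genetic effect between contexts (heterogeneity architecture).
#' @slot corrTol acceptance tolerance on the realized effect correlation.
#' @slot corrBand optional length-2 acceptance band on the realized
#'   correlation (used instead of targetCorr +- corrTol when set).
#' @slot misspecification "none", "single_causal", "epistasis" or "outliers".
#' @slot seed RNG seed.
#' @exportClass SimulationConfig
setClass("SimulationConfig",
         representation(nContexts = "integer", regionVariance = "numeric",
                        sharedBackground = "numeric", hiddenFraction = "numeric",
                        structureFraction = "numeric", nHidden = "integer",
                        architecture = "character", nCausal = "integer",
                        proportionality = "numeric", targetCorr = "numeric",
                        corrTol = "numeric", corrBand = "numeric",
                        misspecification = "character", seed = "integer"))

setValidity("SimulationConfig", function(object) {
  msg <- character(0)
  inUnit <- function(x) x >= 0 && x <= 1
  if (!inUnit(object@regionVariance)) msg <- c(msg, "regionVariance must be in [0,1]")
  if (!inUnit(object@sharedBackground)) msg <- c(msg, "sharedBackground must be in [0,1]")
  if (!inUnit(object@hiddenFraction)) msg <- c(msg, "hiddenFraction must be in [0,1]")
  if (!inUnit(object@structureFraction)) msg <- c(msg, "structureFraction must be in [0,1]")
  if (object@nCausal < 1L) msg <- c(msg, "nCausal must be >= 1")
  if (abs(object@proportionality) > 1) msg <- c(msg, "|proportionality| must be <= 1")
  if (abs(object@targetCorr) > 1) msg <- c(msg, "|targetCorr| must be <= 1")
  if (!object@architecture %in% c("persistent", "rescaling", "heterogeneity"))
    msg <- c(msg, "unknown architecture")
  if (!object@misspecification %in% c("none", "single_causal", "epistasis", "outliers"))
    msg <- c(msg, "unknown misspecification mode")
  if (!length(object@corrBand) %in% c(0L, 2L)) msg <- c(msg, "corrBand must be empty or length 2")
  if (length(msg)) msg else TRUE
})

#' Construct a phenotype simulation configuration
#'
#' @param nContexts,regionVariance,sharedBackground,hiddenFraction,structureFraction,nHidden,architecture,nCausal,proportionality,targetCorr,corrTol,corrBand,misspecification,seed
#'   see the slot documentation of \linkS4class{SimulationConfig}.
#' @return A validated \linkS4class{SimulationConfig}.
#' @export
simulationConfig <- function(nContexts = 2L, regionVariance = 0.02,
                             sharedBackground = 0.6, hiddenFraction = 0.5,
                             structureFraction = 0.2, nHidden = 10L,
                             architecture = c("persistent", "rescaling", "heterogeneity"),
                             nCausal = 4L, proportionality = 0.5,
                             targetCorr = 0, corrTol = 0.05,
                             corrBand = numeric(0),
                             misspecification = c("none", "single_causal",
                                                  "epistasis", "outliers"),
                             seed = 1L) {
  new("SimulationConfig", nContexts = as.integer(nContexts),
      regionVariance = regionVariance, sharedBackground = sharedBackground,
      hiddenFraction = hiddenFraction, structureFraction = structureFraction,
      nHidden = as.integer(nHidden),
      architecture = match.arg(architecture), nCausal = as.integer(nCausal),
      proportionality = proportionality, targetCorr = targetCorr,
      corrTol = corrTol, corrBand = as.numeric(corrBand),
      misspecification = match.arg(misspecification), seed = as.integer(seed))
}

# ---------------------------------------------------------------------------
# PhenotypeBundle
# ---------------------------------------------------------------------------

#' PhenotypeBundle: simulated phenotypes with ground truth
#'
#' @slot Y N x C trait matrix (sum of the stored components).
#' @slot components named list of N x C component matrices
#'   (region, structure, hidden, noise, plus optional extras).
#' @slot fractions named list of per-context variance-fraction vectors, one
#'   entry per component; per context the entries sum to 1.
#' @slot W S x C matrix of true variant effect sizes.
#' @slot causalIndices list of causal variant index vectors per context.
#' @slot config the \linkS4class{SimulationConfig} used.
#' @slot region the \linkS4class{RegionGenotypes} the effects act through.
#' @exportClass PhenotypeBundle
setClass("PhenotypeBundle",
         representation(Y = "matrix", components = "list", fractions = "list",
                        W = "matrix", causalIndices = "list",
                        config = "SimulationConfig", region = "RegionGenotypes"))

# ---------------------------------------------------------------------------
# RegionTestResult / NullPool
# ---------------------------------------------------------------------------

#' RegionTestResult: observed set-test statistics for one region
#'
#' Holds the four fitted covariance-structure models and the three
#' log-likelihood-ratio statistics LLR = 2 * (logLik(full) - logLik(reduced)),
#' clipped at zero: mtSet (full vs null), iSet (full vs block) and iSet-het
#' (full vs rank1).
#'
#' @slot regionId region identifier.
#' @slot fits named list of \linkS4class{FittedModel} for the four kinds.
#' @slot llr named numeric: mtSet, iSet, iSetHet (all >= 0).
#' @slot converged named logical per fitted kind.
#' @exportClass RegionTestResult
setClass("RegionTestResult",
         representation(regionId = "character", fits = "list",
                        llr = "numeric", converged = "logical"))

#' NullPool: pooled null LLR draws across regions
#'
#' @slot llr named list of numeric null LLR vectors, one per test.
#' @slot J replicates per region.
#' @slot T regions contributing to the pool.
#' @slot provenance data.frame with test, region, replicate and seed.
#' @exportClass NullPool
setClass("NullPool",
         representation(llr = "list", J = "integer", T = "integer",
                        provenance = "data.frame"))

# ---------------------------------------------------------------------------
# show methods
# ---------------------------------------------------------------------------

setMethod("show", "DosageMatrix", function(object) {
  cat(sprintf("DosageMatrix: %d individuals x %d variants on chrom %s [%s-%s)\n",
              nrow(object@dosages), ncol(object@dosages), object@chrom,
              format(min(object@positions)), format(max(object@positions) + 1)))
  cat(sprintf("  allele freq range: %.3f-%.3f%s\n",
              min(object@alleleFreqs), max(object@alleleFreqs),
              if (length(object@groups)) sprintf("; %d subpopulations",
                                                 length(unique(object@groups))) else ""))
})

setMethod("show", "RegionGenotypes", function(object) {
  cat(sprintf("RegionGenotypes: %d individuals, S = %d standardized variants (chrom %s)\n",
              nrow(object@G), object@S, object@chrom))
})

setMethod("show", "StudyDesign", function(object) {
  cat(sprintf("StudyDesign (%s): N = %d, C = %d, K = %d covariates\n",
              object@layout, designN(object), object@nContexts, ncol(object@F)))
})

setMethod("show", "FittedModel", function(object) {
  cat(sprintf("FittedModel kind = %s (%s layout): restricted logLik = %.4f%s\n",
              object@kind, object@layout, object@logLik,
              if (object@converged) "" else " [not converged]"))
})

setMethod("show", "RegionTestResult", function(object) {
  cat(sprintf("RegionTestResult %s: LLR mtSet = %.3f, iSet = %.3f, iSet-het = %.3f\n",
              object@regionId, object@llr["mtSet"], object@llr["iSet"],
              object@llr["iSetHet"]))
})

setMethod("show", "NullPool", function(object) {
  cat(sprintf("NullPool: %d tests x %d regions x %d replicates\n",
              length(object@llr), object@T, object@J))
})

# ---------------------------------------------------------------------------
# accessors
# ---------------------------------------------------------------------------

#' @describeIn DosageMatrix-class raw dosage matrix
#' @param x object
#' @export
dosages <- function(x) x@dosages

#' @describeIn DosageMatrix-class 0-based variant positions
#' @export
positions <- function(x) x@positions

#' @describeIn DosageMatrix-class empirical alternate-allele fractions
#' @export
alleleFreqs <- function(x) x@alleleFreqs

#' @describeIn DosageMatrix-class subpopulation labels (or empty)
#' @export
subpopulations <- function(x) x@groups

#' @describeIn RegionGenotypes-class standardized genotype matrix G
#' @param x object
#' @export
genotypes <- function(x) x@G

#' @describeIn RegionGenotypes-class local realized relatedness Rs = G G' / S
#' @export
relatedness <- function(x) x@Rs

#' @describeIn RegionGenotypes-class variant count S
#' @export
nVariants <- function(x) x@S

#' @describeIn StudyDesign-class trait values (N x C matrix for complete
#'   designs and phenotype bundles; observed vector for stratified designs)
#' @param x object
#' @export
phenotypes <- function(x) {
  if (is(x, "PhenotypeBundle")) return(x@Y)
  if (x@layout == "complete") x@Y else x@y
}

#' @describeIn StudyDesign-class fixed-effect covariate matrix
#' @export
covariates <- function(x) x@F

#' @describeIn PhenotypeBundle-class true effect-size matrix W
#' @param x object
#' @export
trueEffects <- function(x) x@W

#' @describeIn PhenotypeBundle-class per-context variance-fraction ledger
#' @export
varianceLedger <- function(x) x@fractions

#' @describeIn RegionTestResult-class named LLR vector
#' @param x object
#' @export
testLLR <- function(x) x@llr
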