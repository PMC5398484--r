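# Synthetic genotype cohorts: mosaic-of-founders genotypes with local LD
# (emulating haplotype sharing in a population cohort) and an LD-free
# binomial mode, plus a two-subpopulation variant for validating the
# principal-component adjustment for population structure.

#' Simulate a mosaic-of-founders genotype cohort with local LD
#'
#' Founder haplotypes are drawn from a shared allele-frequency spectrum
#' (U(mafMin, 0.5)) with spatial autocorrelation along the region: each
#' founder's alleles come from thresholding a latent AR(1) Gaussian process
#' whose correlation decays as exp(-distance/ldScale), giving the founder
#' pool itself realistic haplotype-block structure.  Cohort haplotypes are
#' piecewise copies of founder haplotypes with per-base-pair geometric
#' switch points (exponential inter-switch distances), adding
#' recombination-scale LD decay controlled by \code{recombRate}.  Variants
#' failing the allele-frequency filter are dropped.
#'
#' @param nIndividuals cohort size N.
#' @param nFounders number of founder haplotypes (>= 4).
#' @param nVariants variants drawn uniformly over the region before
#'   filtering.
#' @param regionLengthBp region length in base pairs (0-based half-open
#'   coordinates [startBp, startBp + regionLengthBp)).
#' @param recombRate per-base-pair haplotype switch probability.
#' @param mafMin allele-frequency filter bound (in [0, 0.5)); surviving
#'   variants have empirical alternate-allele frequency in
#'   [mafMin, 1 - mafMin].
#' @param ldScale decay length (bp) of the founder-haplotype
#'   autocorrelation; larger values give stronger, longer-ranged LD.
#' @param seed RNG seed; output is bit-identical for identical seeds.
#' @param chrom chromosome label.
#' @param startBp region start coordinate.
#' @return A \linkS4class{DosageMatrix}.
#' @export
simulateMosaicCohort <- function(nIndividuals, nFounders = 16L,
                                 nVariants = 120L, regionLengthBp = 30000L,
                                 recombRate = 1e-5, mafMin = 0.02,
                                 ldScale = 50000, seed = 1L, chrom = "1",
                                 startBp = 0L) {
  stopifnot(nFounders >= 4 || recombRate == 0, mafMin >= 0, mafMin < 0.5,
            recombRate >= 0, nVariants >= 2)
  withSeed(seed, {
    pos <- startBp + sort(sample.int(regionLengthBp, nVariants)) - 1
    founders <- .founderHaplotypes(nFounders, nVariants, mafMin, pos, ldScale)
    H <- .mosaicHaplotypes(2L * nIndividuals, founders, pos, recombRate)
    dos <- H[seq(1, nrow(H), by = 2), , drop = FALSE] +
           H[seq(2, nrow(H), by = 2), , drop = FALSE]
    .mafFilterDosage(dos, pos, chrom, mafMin)
  })
}

.founderHaplotypes <- function(nFounders, nVariants, mafMin, pos = NULL,
                               ldScale = 0) {
  p <- runif(nVariants, max(mafMin, 0.01), 0.5)
  if (is.null(pos) || ldScale <= 0)
    return(matrix(rbinom(nFounders * nVariants, 1L, rep(p, each = nFounders)),
                  nFounders, nVariants))
  # latent AR(1) Gaussian per founder, thresholded at qnorm(p) per site
  rho <- exp(-diff(pos) / ldScale)
  Z <- matrix(0, nFounders, nVariants)
  Z[, 1] <- rnorm(nFounders)
  for (v in seq_len(nVariants - 1))
    Z[, v + 1] <- rho[v] * Z[, v] + sqrt(1 - rho[v]^2) * rnorm(nFounders)
  H <- matrix(0L, nFounders, nVariants)
  thr <- qnorm(p)
  for (v in seq_len(nVariants)) H[, v] <- as.integer(Z[, v] < thr[v])
  H
}

# column-sweep construction of donor indices: a haplotype keeps its donor
# until a geometric switch, then redraws a donor uniformly
.mosaicHaplotypes <- function(nHap, founders, pos, recombRate) {
  nF <- nrow(founders)
  V <- ncol(founders)
  gaps <- diff(pos)
  pSwitch <- 1 - (1 - recombRate)^gaps
  D <- matrix(0L, nHap, V)
  D[, 1] <- sample.int(nF, nHap, replace = TRUE)
  for (v in seq_len(V - 1)) {
    sw <- stats::runif(nHap) < pSwitch[v]
    D[, v + 1] <- ifelse(sw, sample.int(nF, nHap, replace = TRUE), D[, v])
  }
  matrix(founders[cbind(as.vector(D), rep(seq_len(V), each = nHap))], nHap, V)
}

.mafFilterDosage <- function(dos, pos, chrom, mafMin) {
  f <- colMeans(dos) / 2
  keep <- f >= mafMin & f <= 1 - mafMin
  if (sum(keep) < 2) stop("degenerate region: fewer than 2 variants survive the MAF filter")
  DosageMatrix(dos[, keep, drop = FALSE], pos[keep], chrom = chrom)
}

#' Simulate independent (LD-free) genotypes
#'
#' Each variant is drawn Binomial(2, maf) independently per individual, with
#' no linkage disequilibrium between variants.
#'
#' @param nIndividuals cohort size.
#' @param mafs vector of allele frequencies in (0, 0.5].
#' @param seed RNG seed.
#' @param spacingBp distance between consecutive variants.
#' @param chrom chromosome label.
#' @return A \linkS4class{DosageMatrix}.
#' @export
simulateIndependentGenotypes <- function(nIndividuals, mafs, seed = 1L,
                                         spacingBp = 250L, chrom = "1") {
  if (length(mafs) == 0) stop("mafs must be non-empty")
  stopifnot(all(mafs > 0), all(mafs <= 0.5))
  V <- length(mafs)
  withSeed(seed, {
    dos <- matrix(rbinom(nIndividuals * V, 2L, rep(mafs, each = nIndividuals)),
                  nIndividuals, V)
    DosageMatrix(dos, (seq_len(V) - 1) * spacingBp, chrom = chrom)
  })
}

#' Simulate a cohort with two diverged subpopulations
#'
#' Two founder pools share a base allele-frequency spectrum perturbed in
#' opposite directions with scale \code{divergence}; half the cohort draws
#' its mosaic haplotypes from each pool.  The returned subpopulation labels
#' allow validation of the principal-component adjustment.
#'
#' @inheritParams simulateMosaicCohort
#' @param divergence allele-frequency perturbation scale (>= 0; 0 gives a
#'   homogeneous cohort).
#' @return A \linkS4class{DosageMatrix} with subpopulation labels in
#'   \code{subpopulations()}.
#' @export
twoSubpopulationCohort <- function(nIndividuals, divergence, nFounders = 16L,
                                   nVariants = 120L, regionLengthBp = 30000L,
                                   recombRate = 1e-5, mafMin = 0.02,
                                   ldScale = 50000, seed = 1L, chrom = "1",
                                   startBp = 0L) {
  stopifnot(divergence >= 0)
  n1 <- nIndividuals %/% 2
  n2 <- nIndividuals - n1
  withSeed(seed, {
    pos <- startBp + sort(sample.int(regionLengthBp, nVariants)) - 1
    p <- runif(nVariants, max(mafMin, 0.01), 0.5)
    delta <- divergence * rnorm(nVariants)
    pA <- pmin(pmax(p + delta, 0.005), 0.995)
    pB <- pmin(pmax(p - delta, 0.005), 0.995)
    # shared latent founder process, thresholded at pool-specific
    # frequencies: divergence = 0 yields one homogeneous founder pool
    Zl <- .founderLatent(nFounders, pos, ldScale)
    fA <- .thresholdLatent(Zl, pA)
    fB <- .thresholdLatent(Zl, pB)
    HA <- .mosaicHaplotypes(2L * n1, fA, pos, recombRate)
    HB <- .mosaicHaplotypes(2L * n2, fB, pos, recombRate)
    dos <- rbind(HA[seq(1, 2 * n1, 2), , drop = FALSE] +
                   HA[seq(2, 2 * n1, 2), , drop = FALSE],
                 HB[seq(1, 2 * n2, 2), , drop = FALSE] +
                   HB[seq(2, 2 * n2, 2), , drop = FALSE])
    labels <- c(rep(1L, n1), rep(2L, n2))
    out <- .mafFilterDosage(dos, pos, chrom, mafMin)
    out@groups <- labels
    out
  })
}

# ---------------------------------------------------------------------------
# fixture writers (round-trip through the file readers)
# ---------------------------------------------------------------------------

#' Write a DosageMatrix as a minimal VCF
#'
#' Emits a minimal VCFv4.2 with GT fields (unphased); dummy REF/ALT alleles.
#' Positions are written 1-based per the VCF convention (the in-memory
#' representation is 0-based half-open).
#'
#' @param x a \linkS4class{DosageMatrix}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writeVCF <- function(x, path) {
  d <- x@dosages
  n <- nrow(d)
  gt <- c("0/0", "0/1", "1/1")
  lines <- c("##fileformat=VCFv4.2",
             "##source=iSetR",
             "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
             paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", paste0("S", seq_len(n))),
                   collapse = "\t"))
  body <- vapply(seq_len(ncol(d)), function(v) {
    calls <- ifelse(is.na(d[, v]), "./.", gt[d[, v] + 1L])
    paste(c(x@chrom, format(x@positions[v] + 1, scientific = FALSE),
            paste0("v", v), "A", "G", ".", "PASS", ".", "GT", calls),
          collapse = "\t")
  }, character(1))
  writeLines(c(lines, body), path)
  invisible(path)
}

#' Write a DosageMatrix as tab-separated dosage text
#'
#' Variants as columns with a header row of variant identifiers of the form
#' chrom:pos (0-based); one row per individual.
#'
#' @param x a \linkS4class{DosageMatrix}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writeDosageTSV <- function(x, path) {
  d <- x@dosages
  colnames(d) <- paste0(x@chrom, ":",
                        format(x@positions, scientific = FALSE, trim = TRUE))
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.founderLatent <- function(nFounders, pos, ldScale) {
  V <- length(pos)
  Z <- matrix(rnorm(nFounders * V), nFounders, V)
  if (ldScale > 0) {
    rho <- exp(-diff(pos) / ldScale)
    for (v in seq_len(V - 1))
      Z[, v + 1] <- rho[v] * Z[, v] + sqrt(1 - rho[v]^2) * Z[, v + 1]
  }
  Z
}

.thresholdLatent <- function(Z, p) {
  H <- matrix(0L, nrow(Z), ncol(Z))
  thr <- qnorm(p)
  for (v in seq_len(ncol(Z))) H[, v] <- as.integer(Z[, v] < thr[v])
  H
}
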