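# Genome-scan orchestrator: per-window set tests plus null draws, pooled
# empirical p-values, TSV outputs and a reproducibility log.  Deterministic
# under chunked execution because every window derives its RNG stream from
# (seed, window index).

#' Build or load a scan configuration
#'
#' Configurations are plain named lists; \code{scanConfig} fills defaults
#' and validates, and accepts either a list or a YAML file path (schema
#' version 1).
#'
#' @param config list or YAML path with entries: genotypes (path or
#'   \linkS4class{DosageMatrix}), phenotypes (path, matrix, or
#'   \linkS4class{StudyDesign}), covariates (optional path or matrix),
#'   layout ("complete"/"stratified"), windows (data.frame or BED path;
#'   optional), windowSize (default 100000), windowStep (default 50000),
#'   J (default 30), nPCs (default 10), mafMin (default 0.02),
#'   quantileNormalize (default TRUE), seed (default 1), chunks (default 1),
#'   tests, outDir (optional).
#' @return validated configuration list.
#' @export
scanConfig <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  defaults <- list(layout = "complete", windowSize = 100000,
                   windowStep = 50000, J = 30L, nPCs = 10L, mafMin = 0.02,
                   quantileNormalize = TRUE, seed = 1L, chunks = 1L,
                   tests = c("mtSet", "iSet", "iSetHet"), outDir = NULL,
                   windows = NULL, covariates = NULL, schemaVersion = 1L)
  cfg <- modifyList(defaults, config)
  if (is.null(cfg$genotypes)) stop("config must provide genotypes")
  if (is.null(cfg$phenotypes)) stop("config must provide phenotypes")
  cfg
}

#' Run a sliding-window interaction scan
#'
#' For every window: subset and standardize the region, fit the four
#' covariance models, record the three set-test LLRs and draw J null LLRs
#' per test (permutations for mtSet, parametric bootstraps for iSet and
#' iSet-het); then pool the J*T nulls per test across all windows to obtain
#' empirical p-values, BH q-values per test, and Bonferroni-across-windows
#' FWER values.  Execution can be split into chunks of windows; because all
#' per-window randomness derives from (seed, window index), chunked and
#' serial runs produce byte-identical outputs.
#'
#' @param config see \code{\link{scanConfig}}.
#' @return list with results (data.frame), nullPool (\linkS4class{NullPool})
#'   and log (list); written as TSVs plus a YAML log when outDir is set.
#' @export
runScan <- function(config) {
  cfg <- scanConfig(config)
  geno <- if (is(cfg$genotypes, "DosageMatrix")) cfg$genotypes
          else readGenotypes(cfg$genotypes)
  nMissing <- sum(is.na(geno@dosages))

  # phenotypes
  if (is(cfg$phenotypes, "StudyDesign")) {
    design0 <- cfg$phenotypes
  } else if (cfg$layout == "complete") {
    Y <- if (is.character(cfg$phenotypes)) readPhenotypes(cfg$phenotypes, "complete")
         else as.matrix(cfg$phenotypes)
    design0 <- completeDesign(Y)
  } else {
    ph <- if (is.character(cfg$phenotypes)) readPhenotypes(cfg$phenotypes, "stratified")
          else cfg$phenotypes
    design0 <- stratifiedDesign(ph$value, ph$context)
  }
  N <- designN(design0)
  if (nrow(geno@dosages) != N) {
    gid <- rownames(geno@dosages) %||% paste0("g", seq_len(nrow(geno@dosages)))
    pid <- if (design0@layout == "complete") rownames(design0@Y) else NULL
    stop("sample mismatch between genotypes (", nrow(geno@dosages),
         ") and phenotypes (", N, "); offending ids: ",
         paste(utils::head(setdiff(gid, pid %||% character(0)), 5), collapse = ", "))
  }

  # covariates: intercept + measured + PCs of the genome-wide relatedness
  meas <- if (is.null(cfg$covariates)) NULL
          else if (is.character(cfg$covariates)) readCovariates(cfg$covariates)
          else as.matrix(cfg$covariates)
  pcs <- if (cfg$nPCs > 0) computePCs(geno, min(cfg$nPCs, N - 2L)) else NULL
  F <- buildCovariates(N, measured = meas, pcs = pcs)

  # quantile normalization per context
  if (isTRUE(cfg$quantileNormalize)) {
    if (design0@layout == "complete") {
      design0@Y <- apply(design0@Y, 2, quantileNormalize)
    } else {
      for (a in seq_len(design0@nContexts)) {
        ia <- design0@context == a
        design0@y[ia] <- quantileNormalize(design0@y[ia])
      }
    }
  }
  design0@F <- F
  validObject(design0)

  windows <- if (is.null(cfg$windows)) {
    len <- max(geno@positions) + 1
    makeWindows(setNames(len, geno@chrom), cfg$windowSize, cfg$windowStep)
  } else if (is.character(cfg$windows)) readBED(cfg$windows)
  else cfg$windows

  Tn <- nrow(windows)
  chunkOf <- rep(seq_len(cfg$chunks), length.out = Tn)
  scanOne <- function(w) {
    inWin <- which(geno@positions >= windows$start[w] &
                   geno@positions < windows$end[w] &
                   rep(geno@chrom == windows$chrom[w], length(geno@positions)))
    reg <- tryCatch(
      standardizeRegion(DosageMatrix(geno@dosages[, inWin, drop = FALSE],
                                     geno@positions[inWin], chrom = geno@chrom),
                        cfg$mafMin),
      error = function(e) NULL)
    if (is.null(reg) || reg@S < 2)
      return(list(ok = FALSE, id = windows$id[w], nVar = length(inWin)))
    pre <- .regionPrecompute(design0, reg)
    res <- .testFromPre(pre, windows$id[w],
                        list(seed = childSeed(cfg$seed, w, 1L)))
    nulls <- .nullsFromPre(pre, cfg$J, childSeed(cfg$seed, w, 2L), cfg$tests,
                           list(seed = childSeed(cfg$seed, w, 3L),
                                restarts = 2L))
    list(ok = TRUE, id = windows$id[w], nVar = reg@S, res = res, nulls = nulls)
  }
  chunkRes <- lapply(seq_len(cfg$chunks), function(ch)
    lapply(which(chunkOf == ch), scanOne))
  perWindow <- vector("list", Tn)
  for (ch in seq_len(cfg$chunks))
    perWindow[which(chunkOf == ch)] <- chunkRes[[ch]]

  okIdx <- which(vapply(perWindow, `[[`, TRUE, "ok"))
  if (!length(okIdx)) stop("no testable windows")
  results <- lapply(perWindow[okIdx], `[[`, "res")
  pool <- makeNullPool(lapply(perWindow[okIdx], `[[`, "nulls"),
                       windows$id[okIdx])
  pv <- poolAndPValues(results, pool)

  out <- data.frame(region = windows$id, chrom = windows$chrom,
                    start = windows$start, end = windows$end,
                    n_variants = vapply(perWindow, `[[`, 0L, "nVar"),
                    tested = vapply(perWindow, `[[`, TRUE, "ok"))
  for (col in setdiff(names(pv), "region")) {
    out[[col]] <- NA_real_
    out[[col]][okIdx] <- pv[[col]]
  }
  for (t in cfg$tests) {
    pc <- paste0("p_", t)
    out[[paste0("fwer_", t)]] <- pmin(1, out[[pc]] * length(okIdx))
  }
  out$converged <- NA
  out$converged[okIdx] <- vapply(results, function(r) all(r@converged), TRUE)

  log <- list(schemaVersion = 1L, seed = cfg$seed, J = cfg$J, T = length(okIdx),
              chunks = cfg$chunks, layout = design0@layout, nPCs = cfg$nPCs,
              mafMin = cfg$mafMin, quantileNormalize = cfg$quantileNormalize,
              nMissingDosagesImputed = nMissing,
              packageVersion = as.character(utils::packageVersion("iSetR")),
              coordinateConvention = "0-based half-open",
              windowSeeds = vapply(seq_len(Tn), function(w)
                childSeed(cfg$seed, w, 2L), 0L),
              convergedWindows = sum(out$converged, na.rm = TRUE))

  if (!is.null(cfg$outDir)) {
    dir.create(cfg$outDir, showWarnings = FALSE, recursive = TRUE)
    utils::write.table(format(out, digits = 15, trim = TRUE), file.path(cfg$outDir, "results.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    arch <- .nullArchive(perWindow[okIdx], windows$id[okIdx])
    utils::write.table(format(arch, digits = 15, trim = TRUE), file.path(cfg$outDir, "nullpool.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    yaml::write_yaml(log, file.path(cfg$outDir, "scan_log.yaml"))
  }
  list(results = out, nullPool = pool, log = log)
}

.nullArchive <- function(perWindow, ids) {
  do.call(rbind, lapply(seq_along(perWindow), function(i) {
    nl <- perWindow[[i]]$nulls
    prov <- attr(nl, "provenance")
    prov$region <- ids[i]
    prov$llr <- unlist(nl, use.names = FALSE)
    prov[c("test", "region", "replicate", "llr", "seed")]
  }))
}
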