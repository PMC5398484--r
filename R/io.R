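# File readers and sliding-window generation.  All in-memory and on-disk
# coordinates produced by this package are 0-based half-open; VCF positions
# are converted from/to the 1-based VCF convention at the boundary, and BED
# intervals are taken as-is (BED is natively 0-based half-open).

#' Generate sliding windows over chromosomes
#'
#' Half-open windows [start, start + size) tiled with the given step per
#' chromosome.  Window starts advance until a window reaches the chromosome
#' end; a final partial window is retained (so with size == step the tiling
#' is disjoint and covers every base exactly once).
#'
#' @param chromLengths named numeric vector of chromosome lengths.
#' @param size window size in bp (default 100000).
#' @param step step size in bp (0 < step <= size; default 50000).
#' @return data.frame with chrom, start, end (0-based half-open) and id.
#' @export
makeWindows <- function(chromLengths, size = 100000, step = 50000) {
  stopifnot(step > 0, step <= size)
  if (is.null(names(chromLengths)))
    names(chromLengths) <- as.character(seq_along(chromLengths))
  out <- lapply(names(chromLengths), function(ch) {
    len <- chromLengths[[ch]]
    starts <- seq(0, max(0, len - 1), by = step)
    reach <- which(starts + size >= len)[1]
    if (!is.na(reach)) starts <- starts[seq_len(reach)]
    data.frame(chrom = ch, start = starts, end = pmin(starts + size, len))
  })
  df <- do.call(rbind, out)
  df$id <- paste0(df$chrom, ":", df$start, "-", df$end)
  rownames(df) <- NULL
  df
}

#' Gene-centric testing windows around transcription start sites
#'
#' @param tss numeric vector of 0-based transcription start sites.
#' @param chrom chromosome label(s), recycled.
#' @param flank flanking distance (default 50000, giving 100-kb windows).
#' @return data.frame with chrom, start, end, id.
#' @export
geneWindows <- function(tss, chrom = "1", flank = 50000) {
  start <- pmax(0, tss - flank)
  df <- data.frame(chrom = rep_len(chrom, length(tss)),
                   start = start, end = tss + flank)
  df$id <- paste0(df$chrom, ":", df$start, "-", df$end)
  df
}

#' Read windows from a BED file
#'
#' BED intervals are 0-based half-open, matching the package convention.
#'
#' @param path BED file (at least 3 columns).
#' @return data.frame with chrom, start, end, id.
#' @export
readBED <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE)
  if (ncol(df) < 3) stop("BED file must have at least 3 columns")
  out <- data.frame(chrom = as.character(df[[1]]), start = df[[2]],
                    end = df[[3]])
  out$id <- if (ncol(df) >= 4) as.character(df[[4]])
            else paste0(out$chrom, ":", out$start, "-", out$end)
  out
}

#' Read genotypes from VCF or dosage TSV
#'
#' VCF: GT fields are converted to alternate-allele counts (phased "0|1"
#' and unphased "0/1" both count 1; missing "./." becomes NA); multi-allelic
#' sites are skipped with a warning.  Dosage TSV: variants as columns with a
#' header of chrom:pos identifiers.  Sample order is taken from the file.
#'
#' @param path input file.
#' @param format "auto" (by extension), "vcf" or "dosage".
#' @return A \linkS4class{DosageMatrix}.
#' @export
readGenotypes <- function(path, format = c("auto", "vcf", "dosage")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.vcf(\\.gz)?$", path)) "vcf" else "dosage"
  if (format == "vcf") .readVCFDosages(path) else .readDosageTSV(path)
}

.readVCFDosages <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  multi <- grepl(",", fix[, "ALT"])
  if (any(multi))
    warning(sum(multi), " multi-allelic site(s) skipped")
  gt <- vcfR::extract.gt(v, element = "GT")
  if (is.null(dim(gt))) gt <- matrix(gt, nrow = 1)
  gt <- gt[!multi, , drop = FALSE]
  fix <- fix[!multi, , drop = FALSE]
  if (nrow(gt) == 0) stop("no biallelic variants in VCF")
  dose <- matrix(NA_real_, nrow = ncol(gt), ncol = nrow(gt))
  lookup <- c("0/0" = 0, "0|0" = 0, "0/1" = 1, "1/0" = 1, "0|1" = 1,
              "1|0" = 1, "1/1" = 2, "1|1" = 2)
  for (r in seq_len(nrow(gt))) {
    val <- unname(lookup[gt[r, ]])
    miss <- is.na(gt[r, ]) | gt[r, ] %in% c("./.", ".|.", ".")
    bad <- is.na(val) & !miss
    if (any(bad))
      stop(sprintf("malformed GT field(s) at variant record %d", r))
    dose[, r] <- val
  }
  pos <- as.numeric(fix[, "POS"]) - 1   # VCF is 1-based
  ord <- order(pos)
  DosageMatrix(dose[, ord, drop = FALSE], pos[ord],
               chrom = as.character(fix[ord[1], "CHROM"]))
}

.readDosageTSV <- function(path) {
  df <- tryCatch(utils::read.table(path, sep = "\t", header = TRUE,
                                   check.names = FALSE),
                 error = function(e) stop("malformed dosage TSV: ", conditionMessage(e)))
  m <- as.matrix(df)
  ids <- colnames(m)
  parts <- strsplit(ids, ":", fixed = TRUE)
  bad <- which(vapply(parts, length, 1L) != 2)
  if (length(bad))
    stop(sprintf("malformed dosage header at column %d (expect chrom:pos)", bad[1]))
  pos <- as.numeric(vapply(parts, `[`, "", 2))
  chrom <- vapply(parts, `[`, "", 1)[1]
  ord <- order(pos)
  DosageMatrix(m[, ord, drop = FALSE], pos[ord], chrom = chrom)
}

#' Read a long-format phenotype TSV
#'
#' Expects columns sample_id, context, value.  Complete layout: every sample
#' must appear once per context (rows are reshaped to an N x C matrix).
#' Stratified layout: one row per sample.
#'
#' @param path input TSV.
#' @param layout "complete" or "stratified".
#' @return for "complete", an N x C matrix with sample ids as row names; for
#'   "stratified", a data.frame with sample_id, context, value.
#' @export
readPhenotypes <- function(path, layout = c("complete", "stratified")) {
  layout <- match.arg(layout)
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  need <- c("sample_id", "context", "value")
  if (!all(need %in% names(df)))
    stop("phenotype TSV must have columns: ", paste(need, collapse = ", "))
  if (layout == "stratified") return(df[need])
  ctx <- sort(unique(df$context))
  samples <- unique(df$sample_id)
  Y <- matrix(NA_real_, length(samples), length(ctx),
              dimnames = list(samples, ctx))
  Y[cbind(match(df$sample_id, samples), match(df$context, ctx))] <- df$value
  if (anyNA(Y))
    stop("complete layout requires every sample in every context; missing: ",
         paste(utils::head(samples[rowSums(is.na(Y)) > 0], 5), collapse = ", "))
  Y
}

#' Read a covariate TSV (sample_id plus covariate columns)
#'
#' @param path input TSV.
#' @return numeric matrix with sample ids as row names.
#' @export
readCovariates <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  if (!"sample_id" %in% names(df)) stop("covariate TSV must have a sample_id column")
  m <- as.matrix(df[setdiff(names(df), "sample_id")])
  rownames(m) <- df$sample_id
  m
}
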