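#' Construct a PeakTable from a samples-by-metabolites area matrix
#'
#' @param areas numeric matrix of non-negative integrated peak areas with
#'   samples as rows (rownames = sample ids) and metabolites as columns
#'   (colnames = metabolite ids), matching the on-disk orientation.  Missing
#'   (undetected) cells are \code{NA}; zero is a legal measured value.
#' @param sampleData data.frame with columns \code{sample_id},
#'   \code{genotype} (WT/KO), \code{treatment} (Sal/Sur) and optionally
#'   \code{batch}; one row per sample of \code{areas}.
#' @param internalStandards character vector of metabolite ids that are
#'   stable-isotope internal standards.
#' @return a validated \linkS4class{PeakTable} (stored metabolites x
#'   samples, the Bioconductor convention).
#' @examples
#' a <- matrix(c(10, 20, 1e5, 12, 18, 1e5), nrow = 2, byrow = TRUE,
#'             dimnames = list(c("s1", "s2"), c("m1", "m2", "IS1")))
#' meta <- data.frame(sample_id = c("s1", "s2"), genotype = "KO",
#'                    treatment = c("Sal", "Sur"))
#' PeakTable(a, meta, internalStandards = "IS1")
#' @export
PeakTable <- function(areas, sampleData, internalStandards) {
  areas <- as.matrix(areas)
  mets <- colnames(areas)
  if (is.null(mets)) .stopf("area matrix needs metabolite ids as colnames")
  dup <- unique(mets[duplicated(mets)])
  if (length(dup))
    .stopf("duplicated metabolite id(s): %s", paste(dup, collapse = ", "))
  smp <- rownames(areas)
  if (is.null(smp)) .stopf("area matrix needs sample ids as rownames")
  if (anyDuplicated(smp))
    .stopf("duplicated sample id(s): %s",
           paste(unique(smp[duplicated(smp)]), collapse = ", "))
  if (any(areas < 0, na.rm = TRUE)) {
    bad <- which(areas < 0, arr.ind = TRUE)[1, ]
    .stopf("negative peak area for metabolite '%s' in sample '%s'",
           mets[bad[2]], smp[bad[1]])
  }
  sampleData <- as.data.frame(sampleData)
  missing <- setdiff(smp, sampleData$sample_id)
  if (length(missing))
    .stopf("sample(s) in matrix absent from metadata: %s",
           paste(missing, collapse = ", "))
  sd <- sampleData[match(smp, sampleData$sample_id), , drop = FALSE]
  unknown <- setdiff(internalStandards, mets)
  if (length(unknown))
    .stopf("internal standard(s) not in matrix: %s",
           paste(unknown, collapse = ", "))
  cd <- DataFrame(
    sample_id = smp,
    genotype = as.character(sd$genotype),
    treatment = as.character(sd$treatment),
    group = paste(sd$genotype, sd$treatment, sep = "-"),
    batch = if ("batch" %in% names(sd)) as.character(sd$batch) else NA_character_,
    row.names = smp)
  rd <- DataFrame(is_internal_standard = mets %in% internalStandards,
                  row.names = mets)
  se <- SummarizedExperiment(assays = list(areas = t(areas)),
                             rowData = rd, colData = cd)
  new("PeakTable", se)
}

#' Read a peak-area table with sample metadata and internal-standard flags
#'
#' The matrix file is delimited UTF-8 text (tab default, comma accepted)
#' with a header row of metabolite ids and \code{sample_id} as the first
#' column; empty cells are recorded as missing (not zero).  The metadata
#' file maps \code{sample_id} to genotype, treatment and batch.  Internal
#' standards are listed one id per line.
#'
#' @param path path to the peak-area matrix file.
#' @param metaPath path to the sample-metadata file.
#' @param isPath path to the internal-standard list file.
#' @return a validated \linkS4class{PeakTable}.
#' @seealso \code{\link{writePeakTable}}, \code{\link{PeakTable}}
#' @export
readPeakTable <- function(path, metaPath, isPath) {
  tab <- .readDelim(path)
  if (names(tab)[1] != "sample_id")
    .stopf("first column of '%s' must be sample_id", path)
  mets <- names(tab)[-1]
  dup <- unique(mets[duplicated(mets)])
  if (length(dup))
    .stopf("duplicated metabolite column(s) in '%s': %s", path,
           paste(dup, collapse = ", "))
  m <- as.matrix(tab[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- as.character(tab$sample_id)
  meta <- .readDelim(metaPath)
  is_ids <- readLines(isPath)
  is_ids <- is_ids[nzchar(is_ids)]
  PeakTable(m, meta, internalStandards = is_ids)
}

#' Write a PeakTable to delimited text files
#'
#' Emits the three-file on-disk form read back by
#' \code{\link{readPeakTable}}: the samples-by-metabolites matrix (missing
#' cells written empty), the sample metadata, and the internal-standard id
#' list.  Finite values round-trip at 12 significant digits.
#'
#' @param x a \linkS4class{PeakTable}.
#' @param path,metaPath,isPath output file paths.
#' @return invisibly, \code{path}.
#' @export
writePeakTable <- function(x, path, metaPath, isPath) {
  m <- t(peakAreas(x))  # back to samples-as-rows for the file
  out <- data.frame(sample_id = rownames(m),
                    signif(m, 12), check.names = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  cd <- as.data.frame(colData(x))
  utils::write.table(
    cd[, c("sample_id", "genotype", "treatment", "batch")], metaPath,
    sep = "\t", quote = FALSE, row.names = FALSE, na = "")
  writeLines(rownames(x)[isInternalStandard(x)], isPath)
  invisible(path)
}
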