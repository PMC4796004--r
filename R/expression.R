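## Expression matrix I/O and sample metadata.

#' Read an expression matrix
#'
#' Reads a TSV with genes in rows (first column = locus tag) and samples in
#' columns, optionally attaching per-sample metadata, and returns a
#' [SummarizedExperiment::SummarizedExperiment] with assay \code{"exprs"}.
#' Values are assumed to be normalized log2-scale intensities; pass
#' \code{log2Input = FALSE} for linear-scale data, which is transformed with
#' \code{log2(x + 1)}.
#'
#' @param path expression TSV (header row of sample ids)
#' @param metadataPath optional metadata TSV with columns \code{sample_id},
#'   \code{study_id}, \code{description}
#' @param log2Input is the input already log2 scale?
#' @return SummarizedExperiment with assay \code{exprs} and colData columns
#'   \code{study_id}, \code{description}
#' @export
readExpressionMatrix <- function(path, metadataPath = NULL, log2Input = TRUE) {
  if (!file.exists(path)) stop("expression file not found: ", path)
  tab <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  genes <- as.character(tab[[1]])
  m <- as.matrix(tab[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- genes
  if (!log2Input) m <- log2(m + 1)
  cd <- S4Vectors::DataFrame(study_id = rep(NA_character_, ncol(m)),
                             description = rep(NA_character_, ncol(m)),
                             row.names = colnames(m))
  if (!is.null(metadataPath)) {
    md <- readSampleMetadata(metadataPath)
    idx <- match(colnames(m), md$sample_id)
    if (anyNA(idx))
      stop("metadata lacks sample(s): ",
           paste(head(colnames(m)[is.na(idx)]), collapse = ", "))
    cd$study_id <- md$study_id[idx]
    cd$description <- md$description[idx]
  }
  .newExpressionSE(m, cd)
}

.newExpressionSE <- function(m, colData = NULL) {
  if (anyDuplicated(rownames(m))) stop("duplicate gene ids")
  if (anyDuplicated(colnames(m))) stop("duplicate sample ids")
  if (any(!is.finite(m))) stop("expression values must be finite")
  if (is.null(colData))
    colData <- S4Vectors::DataFrame(study_id = rep(NA_character_, ncol(m)),
                                    description = rep(NA_character_, ncol(m)),
                                    row.names = colnames(m))
  SummarizedExperiment::SummarizedExperiment(
    assays = list(exprs = m), colData = colData)
}

#' Read per-sample metadata
#'
#' @param path TSV with columns \code{sample_id}, \code{study_id},
#'   \code{description}
#' @return data.frame
#' @export
readSampleMetadata <- function(path) {
  if (!file.exists(path)) stop("metadata file not found: ", path)
  md <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("sample_id", "study_id", "description")
  if (!all(need %in% names(md)))
    stop("metadata file must have columns: ", paste(need, collapse = ", "))
  md
}

#' Import a GEO series-matrix style file
#'
#' Thin adapter for the series-matrix flavour of GEO exports: lines beginning
#' \code{!} carry sample annotation, and the expression table sits between
#' \code{!series_matrix_table_begin} and \code{!series_matrix_table_end} with
#' an \code{ID_REF} gene column. Sample titles become \code{description} and
#' \code{!Sample_series_id} (when present) becomes \code{study_id}.
#'
#' @param path series-matrix file (uncompressed)
#' @param log2Input is the table already log2 scale?
#' @return SummarizedExperiment with assay \code{exprs}
#' @export
readGEOSeriesMatrix <- function(path, log2Input = TRUE) {
  if (!file.exists(path)) stop("series matrix file not found: ", path)
  lines <- readLines(path)
  b <- grep("^!series_matrix_table_begin", lines)
  e <- grep("^!series_matrix_table_end", lines)
  if (length(b) != 1L || length(e) != 1L || e <= b)
    stop("not a series-matrix file (missing table markers): ", path)
  tab <- read.delim(text = paste(lines[(b + 1):(e - 1)], collapse = "\n"),
                    check.names = FALSE, stringsAsFactors = FALSE)
  if (names(tab)[1] != "ID_REF") stop("series-matrix table lacks ID_REF column")
  m <- as.matrix(tab[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- as.character(tab[[1]])
  if (!log2Input) m <- log2(m + 1)
  grab <- function(tag) {
    i <- grep(paste0("^!", tag, "\t"), lines)
    if (!length(i)) return(rep(NA_character_, ncol(m)))
    v <- strsplit(lines[i[1]], "\t", fixed = TRUE)[[1]][-1]
    gsub('^"|"$', "", v)[seq_len(ncol(m))]
  }
  acc <- grab("Sample_geo_accession")
  if (!all(is.na(acc))) colnames(m) <- acc
  cd <- S4Vectors::DataFrame(
    study_id = grab("Sample_series_id"),
    description = grab("Sample_title"),
    row.names = colnames(m))
  .newExpressionSE(m, cd)
}

#' Write an expression matrix as TSV
#'
#' @param se SummarizedExperiment with assay \code{exprs}
#' @param path output path
#' @return \code{path}, invisibly
#' @export
writeExpressionMatrix <- function(se, path) {
  m <- SummarizedExperiment::assay(se, "exprs")
  out <- data.frame(locus_tag = rownames(m), m, check.names = FALSE,
                    stringsAsFactors = FALSE)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write sample metadata as TSV
#'
#' @param se SummarizedExperiment carrying \code{study_id} and
#'   \code{description} in its colData
#' @param path output path
#' @return \code{path}, invisibly
#' @export
writeSampleMetadata <- function(se, path) {
  cd <- SummarizedExperiment::colData(se)
  out <- data.frame(sample_id = rownames(cd), study_id = cd$study_id,
                    description = cd$description, stringsAsFactors = FALSE)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
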