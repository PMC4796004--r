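## Expression binarization: deterministic per-gene two-cluster split.

## Optimal 1-D two-cluster split of a numeric vector: over the n-1 cuts of the
## sorted values, minimize total within-cluster sum of squares. Deterministic
## (smallest cut index wins ties). Returns the cut (low cluster = sorted
## values 1..k), the two cluster means and the boundary midpoint.
.bestSplit <- function(x) {
  n <- length(x)
  s <- sort(x)
  cs <- cumsum(s)
  cs2 <- cumsum(s * s)
  k <- seq_len(n - 1L)
  ssLow <- cs2[k] - cs[k]^2 / k
  nHigh <- n - k
  sumHigh <- cs[n] - cs[k]
  ssHigh <- (cs2[n] - cs2[k]) - sumHigh^2 / nHigh
  tot <- ssLow + ssHigh
  kbest <- which.min(tot)  # first minimum: deterministic
  list(
    k = kbest,
    meanLow = cs[kbest] / kbest,
    meanHigh = (cs[n] - cs[kbest]) / (n - kbest),
    midpoint = (s[kbest] + s[kbest + 1L]) / 2
  )
}

#' Binarize an expression matrix into ON/OFF/UNCERTAIN calls
#'
#' Per gene, the normalized expression values are split into two clusters by
#' the exhaustive variance-minimizing cut of the sorted values (no random
#' initialization). When the two cluster means are separated by at least
#' \code{minSeparation} log2 units the gene is treated as bimodal: samples
#' above the boundary midpoint are called ON, below OFF, and samples within
#' \code{uncertainBand} of the midpoint are left UNCERTAIN. When the
#' variance-minimizing cut is unseparated, the gene is re-examined at the
#' largest discontinuity of its sorted values: if that single gap reaches
#' \code{minSeparation} the gene is split there instead. This rescues genes
#' that are ON (or OFF) in only a handful of samples, where the
#' variance-minimizing cut bisects the majority mode; a pure-noise gene
#' essentially never shows such a discontinuity. Otherwise the gene is
#' unimodal: all samples are called ON when the gene's median lies at or
#' above the \code{globalOnQuantile} quantile of the whole matrix, else all
#' OFF. Constant genes are unimodal by construction.
#'
#' @param se SummarizedExperiment with assay \code{exprs} (log2 scale), or a
#'   numeric matrix
#' @param minSeparation minimal distance (log2 units) between cluster means
#'   for a gene to count as bimodal
#' @param uncertainBand half-width (log2 units) of the guard band around the
#'   split midpoint inside which calls are UNCERTAIN; 0 recovers a strictly
#'   binary model. The default, half of \code{minSeparation}, covers the
#'   noise overlap region between two modes that are just separable
#' @param globalOnQuantile quantile of all matrix values against which a
#'   unimodal gene's median decides always-ON vs always-OFF
#' @return a [BinaryStateMatrix-class]
#' @export
binarizeExpression <- function(se, minSeparation = 1.0, uncertainBand = 0.5,
                               globalOnQuantile = 0.40) {
  m <- if (is(se, "SummarizedExperiment"))
    SummarizedExperiment::assay(se, "exprs") else as.matrix(se)
  if (ncol(m) < 2L) stop("binarization needs at least 2 samples")
  if (is.null(colnames(m))) colnames(m) <- sprintf("S%03d", seq_len(ncol(m)))
  if (is.null(rownames(m))) rownames(m) <- sprintf("g%d", seq_len(nrow(m)))
  globalThreshold <- quantile(m, globalOnQuantile, names = FALSE)
  out <- matrix(NA_integer_, nrow(m), ncol(m), dimnames = dimnames(m))
  for (i in seq_len(nrow(m))) {
    x <- m[i, ]
    if (max(x) == min(x)) {
      out[i, ] <- if (x[1] >= globalThreshold) 1L else 0L
      next
    }
    sp <- .bestSplit(x)
    if (sp$meanHigh - sp$meanLow < minSeparation) {
      ## Variance-minimizing cuts bisect the majority mode when one state is
      ## very rare (ON in a handful of samples). Rescue: split at the largest
      ## discontinuity of the sorted values when that gap alone exceeds the
      ## separation threshold (the cluster-mean gap is then >= it, too).
      s <- sort(x)
      gaps <- diff(s)
      kg <- which.max(gaps)
      if (gaps[kg] >= minSeparation) {
        sp <- list(k = kg, meanLow = mean(s[seq_len(kg)]),
                   meanHigh = mean(s[-seq_len(kg)]),
                   midpoint = (s[kg] + s[kg + 1L]) / 2)
      } else {
        out[i, ] <- if (median(x) >= globalThreshold) 1L else 0L
        next
      }
    }
    geneCalls <- ifelse(x >= sp$midpoint, 1L, 0L)
    geneCalls[abs(x - sp$midpoint) < uncertainBand] <- NA_integer_
    out[i, ] <- geneCalls
  }
  cd <- if (is(se, "SummarizedExperiment")) SummarizedExperiment::colData(se)
        else S4Vectors::DataFrame(row.names = colnames(m))
  new("BinaryStateMatrix",
      SummarizedExperiment::SummarizedExperiment(
        assays = list(calls = out), colData = cd))
}

#' @rdname BinaryStateMatrix-class
#' @export
setMethod("calls", "BinaryStateMatrix", function(x)
  SummarizedExperiment::assay(x, "calls"))

#' Build a BinaryStateMatrix from a call matrix
#'
#' @param m integer matrix (1 = ON, 0 = OFF, NA = UNCERTAIN) with gene
#'   rownames and sample colnames
#' @param colData optional per-sample DataFrame
#' @return a [BinaryStateMatrix-class]
#' @export
BinaryStateMatrix <- function(m, colData = NULL) {
  storage.mode(m) <- "integer"
  if (is.null(colData))
    colData <- S4Vectors::DataFrame(row.names = colnames(m))
  new("BinaryStateMatrix",
      SummarizedExperiment::SummarizedExperiment(
        assays = list(calls = m), colData = colData))
}

#' @describeIn stateCounts per-gene tallies of ON/OFF/UNCERTAIN
#' @export
setMethod("stateCounts", "BinaryStateMatrix", function(x) {
  m <- calls(x)
  on <- rowSums(m == 1L, na.rm = TRUE)
  off <- rowSums(m == 0L, na.rm = TRUE)
  data.frame(locus_tag = rownames(m), on = as.integer(on),
             off = as.integer(off),
             uncertain = as.integer(ncol(m) - on - off),
             row.names = NULL, stringsAsFactors = FALSE)
})

#' @describeIn changedState genes decided in both samples with opposite calls
#' @export
setMethod("changedState", "BinaryStateMatrix",
          function(x, sampleA, sampleB) {
  m <- calls(x)
  for (s in c(sampleA, sampleB))
    if (!s %in% colnames(m)) stop("unknown sample id: ", s)
  a <- m[, sampleA]
  b <- m[, sampleB]
  sort(rownames(m)[!is.na(a) & !is.na(b) & a != b])
})

#' @rdname BinaryStateMatrix-class
#' @export
setMethod("show", "BinaryStateMatrix", function(object) {
  m <- calls(object)
  cat("BinaryStateMatrix:", nrow(m), "genes x", ncol(m), "samples\n")
  cat(sprintf("  calls: %d ON, %d OFF, %d UNCERTAIN\n",
              sum(m == 1L, na.rm = TRUE), sum(m == 0L, na.rm = TRUE),
              sum(is.na(m))))
})

#' Write calls as TSV
#'
#' Calls are serialized as \code{1} (ON), \code{0} (OFF) and \code{?}
#' (UNCERTAIN).
#'
#' @param x a [BinaryStateMatrix-class]
#' @param path output path
#' @return \code{path}, invisibly
#' @export
writeCalls <- function(x, path) {
  m <- calls(x)
  ch <- matrix(as.character(m), nrow(m), ncol(m), dimnames = dimnames(m))
  ch[is.na(m)] <- "?"
  out <- data.frame(locus_tag = rownames(m), ch, check.names = FALSE,
                    stringsAsFactors = FALSE)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read calls written by [writeCalls()]
#'
#' @param path TSV path
#' @return a [BinaryStateMatrix-class]
#' @export
readCalls <- function(path) {
  if (!file.exists(path)) stop("calls file not found: ", path)
  tab <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                    colClasses = "character")
  m <- as.matrix(tab[, -1, drop = FALSE])
  rownames(m) <- tab[[1]]
  mi <- suppressWarnings(matrix(as.integer(m), nrow(m), ncol(m),
                                dimnames = dimnames(m)))
  BinaryStateMatrix(mi)
}
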