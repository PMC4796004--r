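## Atomic Regulon inference: decompose draft regulons by binary-profile
## identity, expand across drafts, score members by average PCC.

#' Are two binary call profiles identical?
#'
#' Two call vectors are identical in the AR sense when no sample has one gene
#' ON and the other OFF, and at least \code{minCodecided} samples are decided
#' (non-UNCERTAIN) in both. UNCERTAIN calls never conflict.
#'
#' @param a,b integer call vectors (1 = ON, 0 = OFF, NA = UNCERTAIN) of equal
#'   length
#' @param minCodecided minimum number of co-decided samples
#' @return logical scalar
#' @export
profilesIdentical <- function(a, b, minCodecided = 10L) {
  if (length(a) != length(b))
    stop("call vectors have different lengths (", length(a), " vs ",
         length(b), ")")
  conflict <- any((a == 1L & b == 0L) | (a == 0L & b == 1L), na.rm = TRUE)
  if (conflict) return(FALSE)
  sum(!is.na(a) & !is.na(b)) >= minCodecided
}

## Row-standardize so that tcrossprod gives Pearson correlations:
## z = (x - mean) / (sd * sqrt(n - 1)); constant rows become zero vectors
## (correlation 0 with everything).
.standardizeRows <- function(m) {
  mu <- rowMeans(m)
  ctr <- m - mu
  ss <- sqrt(rowSums(ctr^2))
  ss[ss == 0] <- Inf
  ctr / ss
}

#' Construct an AtomicRegulonSet
#'
#' Low-level constructor, mainly for encoding published AR tables as fixtures
#' and for testing; inference builds these via [inferAtomicRegulons()].
#'
#' @param membership data.frame with columns \code{ar_id} (integer),
#'   \code{locus_tag} and optionally \code{avg_pcc}
#' @param consensus optional integer matrix (ARs x samples), rownames = AR ids
#' @param onCount,offCount optional per-AR counts, used when no consensus
#'   matrix is available (e.g. encoding a printed table); derived from the
#'   consensus otherwise
#' @param unplaced genes reported as unplaced
#' @param labels optional per-AR labels
#' @return an [AtomicRegulonSet-class]
#' @export
AtomicRegulonSet <- function(membership, consensus = NULL, onCount = NULL,
                             offCount = NULL, unplaced = character(),
                             labels = NULL) {
  membership <- as.data.frame(membership, stringsAsFactors = FALSE)
  if (is.null(membership$avg_pcc)) membership$avg_pcc <- NA_real_
  membership$ar_id <- as.integer(membership$ar_id)
  membership <- membership[order(membership$ar_id), , drop = FALSE]
  rownames(membership) <- NULL
  ids <- sort(unique(membership$ar_id))
  k <- length(ids)
  if (is.null(consensus)) {
    consensus <- matrix(NA_integer_, k, 0)
    rownames(consensus) <- as.character(ids)
  } else {
    storage.mode(consensus) <- "integer"
    consensus <- consensus[as.character(ids), , drop = FALSE]
  }
  if (ncol(consensus)) {
    onCount <- as.integer(rowSums(consensus == 1L, na.rm = TRUE))
    offCount <- as.integer(rowSums(consensus == 0L, na.rm = TRUE))
  } else {
    if (is.null(onCount)) onCount <- rep(0L, k)
    if (is.null(offCount)) offCount <- rep(0L, k)
  }
  if (is.null(labels)) labels <- rep(NA_character_, k)
  new("AtomicRegulonSet", membership = membership, consensus = consensus,
      onCount = as.integer(onCount), offCount = as.integer(offCount),
      unplaced = as.character(unplaced), labels = as.character(labels))
}

#' Infer Atomic Regulons from draft regulons and binarized expression
#'
#' Three deterministic stages. Decompose: within each draft regulon, genes are
#' greedily grouped in genome order (matrix row order) into maximal sets whose
#' members pairwise satisfy [profilesIdentical()]. Expand: whole groups are
#' merged across drafts, in ascending first-locus order, when their consensus
#' profiles satisfy [profilesIdentical()] and every gene's post-merge average
#' Pearson correlation with its co-members stays at or above
#' \code{minAvgPcc}; the correlation gate applies to merges only, never to
#' within-draft decomposition. Finally, groups smaller than \code{minSize}
#' are set aside as unplaced genes, consecutive AR ids are assigned in genome
#' order, each member's average PCC is computed on the continuous expression
#' over all samples, and each AR's consensus call per sample is the members'
#' shared decided state (UNCERTAIN when no member is decided).
#'
#' @param drafts list of draft regulons ([buildDraftRegulons()]) or plain
#'   list of locus-tag vectors
#' @param bsm a [BinaryStateMatrix-class] covering all draft genes
#' @param expr SummarizedExperiment (assay \code{exprs}) or numeric matrix
#'   with the same genes
#' @param minSize smallest reported AR (genes in smaller groups are unplaced)
#' @param minAvgPcc average-PCC gate on cross-draft merges
#' @param minCodecided see [profilesIdentical()]
#' @return an [AtomicRegulonSet-class]
#' @export
inferAtomicRegulons <- function(drafts, bsm, expr, minSize = 2L,
                                minAvgPcc = 0.6, minCodecided = 10L) {
  callsM <- calls(bsm)
  exprM <- if (is(expr, "SummarizedExperiment"))
    SummarizedExperiment::assay(expr, "exprs") else as.matrix(expr)
  geneSets <- lapply(drafts, function(d) if (is.list(d)) d$genes else d)
  genes <- unlist(geneSets, use.names = FALSE)
  if (anyDuplicated(genes))
    stop("gene(s) appear in more than one draft: ",
         paste(head(unique(genes[duplicated(genes)])), collapse = ", "))
  miss <- setdiff(genes, rownames(callsM))
  if (length(miss))
    stop("draft gene(s) absent from the call matrix: ",
         paste(head(miss), collapse = ", "))
  noExpr <- setdiff(genes, rownames(exprM))
  if (length(noExpr))
    stop("gene(s) in calls but absent from expression: ",
         paste(head(noExpr), collapse = ", "))

  nS <- ncol(callsM)
  rowOf <- setNames(seq_len(nrow(callsM)), rownames(callsM))
  ## sign encoding: ON = 1, OFF = -1, UNCERTAIN = 0
  sgn <- callsM
  sgn[is.na(sgn)] <- 99L
  sgn <- matrix(c(0L, -1L, 1L)[match(sgn, c(99L, 0L, 1L))],
                nrow(callsM), nS, dimnames = dimnames(callsM))
  Z <- .standardizeRows(exprM[rownames(callsM), colnames(callsM),
                              drop = FALSE])

  ## Stage 1: decompose each draft in genome order
  groups <- list()
  for (gs in geneSets) {
    gs <- gs[order(rowOf[gs])]
    local_groups <- list()
    for (g in gs) {
      v <- sgn[rowOf[g], ]
      placed <- FALSE
      for (j in seq_along(local_groups)) {
        M <- sgn[local_groups[[j]], , drop = FALSE]
        conf <- rowSums((M == 1L) & rep(v == -1L, each = nrow(M))) +
                rowSums((M == -1L) & rep(v == 1L, each = nrow(M)))
        codec <- rowSums((M != 0L) & rep(v != 0L, each = nrow(M)))
        if (all(conf == 0L) && all(codec >= minCodecided)) {
          local_groups[[j]] <- c(local_groups[[j]], rowOf[[g]])
          placed <- TRUE
          break
        }
      }
      if (!placed) local_groups[[length(local_groups) + 1L]] <- rowOf[[g]]
    }
    groups <- c(groups, local_groups)
  }

  ## group consensus in sign encoding: members agree on decided samples
  gCons <- lapply(groups, function(idx) {
    M <- sgn[idx, , drop = FALSE]
    up <- apply(M, 2, max)
    dn <- apply(M, 2, min)
    ifelse(up == 1L, 1L, ifelse(dn == -1L, -1L, 0L))
  })
  ord <- order(vapply(groups, min, integer(1)))
  groups <- groups[ord]
  gCons <- gCons[ord]

  ## Stage 2: greedy expansion across drafts, ascending first-locus order
  nG <- length(groups)
  P <- matrix(0L, nG, nS)  # cluster consensus == ON
  N <- matrix(0L, nG, nS)  # cluster consensus == OFF
  clIdx <- vector("list", nG)
  clCons <- vector("list", nG)
  clZsum <- vector("list", nG)
  K <- 0L
  for (i in seq_len(nG)) {
    v <- gCons[[i]]
    idx <- groups[[i]]
    zsum <- if (length(idx) == 1L) Z[idx, ] else colSums(Z[idx, , drop = FALSE])
    merged <- FALSE
    if (K > 0L) {
      conf <- P[seq_len(K), , drop = FALSE] %*% (v == -1L) +
              N[seq_len(K), , drop = FALSE] %*% (v == 1L)
      codec <- (P[seq_len(K), , drop = FALSE] +
                N[seq_len(K), , drop = FALSE]) %*% (v != 0L)
      for (k in which(conf == 0 & codec >= minCodecided)) {
        mIdx <- c(clIdx[[k]], idx)
        zs <- clZsum[[k]] + zsum
        avg <- (Z[mIdx, , drop = FALSE] %*% zs - 1) / (length(mIdx) - 1L)
        if (min(avg) >= minAvgPcc) {
          clIdx[[k]] <- mIdx
          clZsum[[k]] <- zs
          cons <- clCons[[k]]
          cons[cons == 0L] <- v[cons == 0L]
          clCons[[k]] <- cons
          P[k, ] <- as.integer(cons == 1L)
          N[k, ] <- as.integer(cons == -1L)
          merged <- TRUE
          break
        }
      }
    }
    if (!merged) {
      K <- K + 1L
      clIdx[[K]] <- idx
      clCons[[K]] <- v
      clZsum[[K]] <- zsum
      P[K, ] <- as.integer(v == 1L)
      N[K, ] <- as.integer(v == -1L)
    }
  }
  clIdx <- clIdx[seq_len(K)]
  clCons <- clCons[seq_len(K)]

  ## Stage 3: drop undersized groups, assign ids, score members
  keep <- which(lengths(clIdx) >= minSize)
  unplacedIdx <- unlist(clIdx[setdiff(seq_len(K), keep)])
  keep <- keep[order(vapply(clIdx[keep], min, integer(1)))]
  mem <- list()
  consMat <- matrix(NA_integer_, length(keep), nS,
                    dimnames = list(as.character(seq_along(keep)),
                                    colnames(callsM)))
  for (a in seq_along(keep)) {
    k <- keep[a]
    idx <- sort(clIdx[[k]])
    m <- length(idx)
    zs <- colSums(Z[idx, , drop = FALSE])
    avg <- as.numeric(Z[idx, , drop = FALSE] %*% zs - 1) / (m - 1L)
    mem[[a]] <- data.frame(ar_id = a, locus_tag = rownames(callsM)[idx],
                           avg_pcc = avg, stringsAsFactors = FALSE)
    cons <- clCons[[k]]
    consMat[a, ] <- ifelse(cons == 1L, 1L, ifelse(cons == -1L, 0L,
                                                  NA_integer_))
  }
  membership <- if (length(mem)) do.call(rbind, mem)
    else data.frame(ar_id = integer(), locus_tag = character(),
                    avg_pcc = numeric(), stringsAsFactors = FALSE)
  AtomicRegulonSet(membership, consensus = consMat,
                   unplaced = sort(rownames(callsM)[unplacedIdx]))
}

#' @rdname AtomicRegulonSet-class
#' @export
setMethod("arIds", "AtomicRegulonSet", function(x)
  sort(unique(x@membership$ar_id)))

#' @rdname AtomicRegulonSet-class
#' @export
setMethod("arGenes", "AtomicRegulonSet", function(x)
  lapply(split(x@membership$locus_tag, x@membership$ar_id), sort))

#' @rdname AtomicRegulonSet-class
#' @export
setMethod("arMembership", "AtomicRegulonSet", function(x) x@membership)

#' @rdname AtomicRegulonSet-class
#' @export
setMethod("consensusProfile", "AtomicRegulonSet", function(x) x@consensus)

#' @rdname AtomicRegulonSet-class
#' @export
setMethod("onCount", "AtomicRegulonSet", function(x)
  setNames(x@onCount, rownames(x@consensus)))

#' @rdname AtomicRegulonSet-class
#' @export
setMethod("offCount", "AtomicRegulonSet", function(x)
  setNames(x@offCount, rownames(x@consensus)))

#' @rdname AtomicRegulonSet-class
#' @export
setMethod("unplaced", "AtomicRegulonSet", function(x) x@unplaced)

#' @rdname AtomicRegulonSet-class
#' @export
setMethod("show", "AtomicRegulonSet", function(object) {
  k <- length(unique(object@membership$ar_id))
  cat("AtomicRegulonSet:", k, "ARs,", nrow(object@membership),
      "member genes,", length(object@unplaced), "unplaced\n")
  if (k) {
    sz <- table(object@membership$ar_id)
    cat("  AR sizes:", paste(range(sz), collapse = "-"),
        sprintf("(median %.0f)", median(sz)), "\n")
  }
})

#' @describeIn categorizeARs classification from the consensus ON/OFF counts
#' @export
setMethod("categorizeARs", "AtomicRegulonSet", function(ars) {
  ids <- rownames(ars@consensus)
  on <- ars@onCount
  off <- ars@offCount
  always_on <- ids[off == 0L & on > 0L]
  always_off <- ids[on == 0L & off > 0L]
  differential <- setdiff(ids, c(always_on, always_off))
  sz <- table(ars@membership$ar_id)
  nGenes <- function(set) if (length(set)) sum(sz[set]) else 0L
  list(always_on = always_on, always_off = always_off,
       differential = differential,
       gene_counts = c(always_on = nGenes(always_on),
                       always_off = nGenes(always_off),
                       differential = nGenes(differential)))
})

#' Write an AR table as TSV
#'
#' One row per member gene: \code{ar_id}, \code{locus_tag}, \code{gene_name},
#' \code{avg_pcc}, \code{on_count}, \code{off_count}, \code{label}. Rows are
#' sorted by (ar_id, locus_tag) for stable diffs.
#'
#' @param ars an [AtomicRegulonSet-class]
#' @param path output path
#' @param features optional GRanges supplying gene names
#' @return \code{path}, invisibly
#' @export
writeAtomicRegulons <- function(ars, path, features = NULL) {
  mb <- ars@membership
  ids <- rownames(ars@consensus)
  on <- setNames(ars@onCount, ids)
  off <- setNames(ars@offCount, ids)
  lab <- setNames(ars@labels, ids)
  nm <- mb$locus_tag
  if (!is.null(features)) {
    i <- match(mb$locus_tag, features$locus_tag)
    nm <- ifelse(is.na(i), mb$locus_tag, features$name[i])
  }
  out <- data.frame(ar_id = mb$ar_id, locus_tag = mb$locus_tag,
                    gene_name = nm, avg_pcc = round(mb$avg_pcc, 4),
                    on_count = on[as.character(mb$ar_id)],
                    off_count = off[as.character(mb$ar_id)],
                    label = lab[as.character(mb$ar_id)],
                    stringsAsFactors = FALSE)
  out <- out[order(out$ar_id, out$locus_tag), , drop = FALSE]
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "")
  invisible(path)
}

#' Adjusted Rand index between two gene partitions
#'
#' Agreement between two partitions of the same genes, e.g. an inferred AR
#' partition against a planted ground truth; 1 means identical partitions, 0
#' is chance-level agreement. Genes present in only one labelling are dropped.
#'
#' @param a,b named label vectors (names = locus tags)
#' @return numeric scalar
#' @export
partitionARI <- function(a, b) {
  common <- intersect(names(a), names(b))
  if (!length(common)) stop("no genes in common between the two partitions")
  mclust::adjustedRandIndex(as.character(a[common]), as.character(b[common]))
}
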