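## Reconciliation of ARs with the regulatory network: stimulus signatures,
## theoretical ARs, four-way consistency, curation operators, metadata
## enrichment, essential-gene check.

#' Per-gene stimulus signatures
#'
#' A gene's stimulus signature is its set of (stimulus, sign) pairs in the
#' network. Multiple links of one gene to the same stimulus are reduced to a
#' single pair: a known sign wins over \code{unknown}, and contradictory known
#' signs are kept as the token \code{conflict}.
#'
#' @param net a [RegulatoryNetwork-class]
#' @param genes locus tags to look up
#' @return named list (one element per gene) of data.frames with columns
#'   \code{stimulus_id} and \code{sign}; zero-row for genes with no stimuli
#' @export
stimulusSignatures <- function(net, genes) {
  lnk <- links(net)
  lnk <- lnk[!is.na(lnk$stimulus_id) & lnk$target_gene %in% genes, ,
             drop = FALSE]
  out <- setNames(vector("list", length(genes)), genes)
  empty <- data.frame(stimulus_id = character(), sign = character(),
                      stringsAsFactors = FALSE)
  sp <- split(lnk[c("stimulus_id", "sign")], lnk$target_gene)
  for (g in genes) {
    df <- sp[[g]]
    if (is.null(df) || !nrow(df)) { out[[g]] <- empty; next }
    red <- lapply(split(df$sign, df$stimulus_id), function(s) {
      s <- unique(s[s != "unknown"])
      if (length(s) == 0L) "unknown" else if (length(s) == 1L) s
      else "conflict"
    })
    out[[g]] <- data.frame(stimulus_id = names(red),
                           sign = unlist(red, use.names = FALSE),
                           stringsAsFactors = FALSE)
  }
  out
}

## exact signature key (used for grouping into theoretical ARs)
.signatureKey <- function(sig) {
  if (!nrow(sig)) return("")
  paste(sort(paste(sig$stimulus_id, sig$sign, sep = "|")), collapse = ";")
}

## wildcard signature equality (used for consistency): stimulus sets must
## match; signs must match unless either is unknown
.signaturesCompatible <- function(a, b) {
  if (!setequal(a$stimulus_id, b$stimulus_id)) return(FALSE)
  if (!nrow(a)) return(TRUE)
  sa <- setNames(a$sign, a$stimulus_id)
  sb <- setNames(b$sign, b$stimulus_id)
  s <- names(sa)
  all(sa[s] == sb[s] | sa[s] == "unknown" | sb[s] == "unknown")
}

#' Theoretical ARs from network stimulus structure
#'
#' Groups genes into equivalence classes of equal stimulus signature: genes
#' responding to identical sets of stimuli with identical induction/suppression
#' profiles form one theoretical AR. Classes smaller than \code{minSize} are
#' reported as unplaced; genes with no stimulus links carry no information and
#' are reported separately.
#'
#' @param net a [RegulatoryNetwork-class]
#' @param universe locus tags to partition (must be known to the network)
#' @param minSize smallest reported class
#' @return list with \code{classes} (named list of locus-tag vectors),
#'   \code{unplaced} (genes in undersized classes), \code{no_stimulus}
#'   (genes with empty signatures) and \code{n_signatures} (number of
#'   distinct non-empty signatures in the universe)
#' @export
theoreticalARs <- function(net, universe, minSize = 2L) {
  bad <- setdiff(universe, networkGenes(net))
  if (length(bad))
    stop("universe gene(s) unknown to the network: ",
         paste(head(bad), collapse = ", "))
  sigs <- stimulusSignatures(net, universe)
  keys <- vapply(sigs, .signatureKey, character(1))
  no_stim <- universe[keys == ""]
  withSig <- universe[keys != ""]
  grp <- split(withSig, keys[keys != ""])
  sizes <- lengths(grp)
  classes <- grp[sizes >= minSize]
  ## stable class order: by first member's position in the universe
  if (length(classes)) {
    first <- vapply(classes, function(g) min(match(g, universe)), integer(1))
    classes <- lapply(classes[order(first)], function(g)
      g[order(match(g, universe))])
    names(classes) <- sprintf("theoretical_ar_%d", seq_along(classes))
  } else {
    classes <- setNames(list(), character())
  }
  list(classes = classes,
       unplaced = sort(unlist(grp[sizes < minSize], use.names = FALSE)),
       no_stimulus = sort(no_stim),
       n_signatures = length(unique(keys[keys != ""])))
}

.classifyGeneSet <- function(genes, net) {
  sigs <- stimulusSignatures(net, genes)
  nonEmpty <- sigs[vapply(sigs, nrow, integer(1)) > 0L]
  if (!length(nonEmpty))
    return(list(category = "empty", sigs = sigs))
  agree <- TRUE
  if (length(nonEmpty) > 1L) {
    for (i in seq_len(length(nonEmpty) - 1L)) {
      for (j in seq(i + 1L, length(nonEmpty))) {
        if (!.signaturesCompatible(nonEmpty[[i]], nonEmpty[[j]])) {
          agree <- FALSE
          break
        }
      }
      if (!agree) break
    }
  }
  category <- if (!agree) "inconsistent"
    else if (length(nonEmpty) == length(sigs)) "consistent"
    else "consistent_missing"
  list(category = category, sigs = sigs)
}

#' @describeIn classifyConsistency per-AR category vector
#' @export
setMethod("classifyConsistency",
          signature("AtomicRegulonSet", "RegulatoryNetwork"),
          function(ars, net) {
  gsets <- arGenes(ars)
  vapply(gsets, function(g) .classifyGeneSet(g, net)$category, character(1))
})

#' @describeIn consistencyReport build the full report
#' @export
setMethod("consistencyReport",
          signature("AtomicRegulonSet", "RegulatoryNetwork"),
          function(ars, net) {
  gsets <- arGenes(ars)
  cats <- c("consistent", "consistent_missing", "inconsistent", "empty")
  rows <- vector("list", length(gsets))
  wit <- setNames(vector("list", length(gsets)), names(gsets))
  for (i in seq_along(gsets)) {
    cl <- .classifyGeneSet(gsets[[i]], net)
    keys <- vapply(cl$sigs, .signatureKey, character(1))
    rows[[i]] <- data.frame(
      ar_id = as.integer(names(gsets)[i]),
      category = cl$category,
      n_members = length(gsets[[i]]),
      n_empty = sum(keys == ""),
      n_signatures = length(unique(keys[keys != ""])),
      stringsAsFactors = FALSE)
    wit[[i]] <- keys
  }
  perAR <- if (length(rows)) do.call(rbind, rows)
    else data.frame(ar_id = integer(), category = character(),
                    n_members = integer(), n_empty = integer(),
                    n_signatures = integer(), stringsAsFactors = FALSE)
  summary <- data.frame(
    category = cats,
    count = as.integer(table(factor(perAR$category, levels = cats))),
    stringsAsFactors = FALSE)
  new("ConsistencyReport", perAR = perAR, summary = summary, witnesses = wit)
})

#' @rdname ConsistencyReport-class
#' @param object a \code{ConsistencyReport}
#' @export
setMethod("show", "ConsistencyReport", function(object) {
  cat("ConsistencyReport over", nrow(object@perAR), "ARs\n")
  s <- object@summary
  for (i in seq_len(nrow(s)))
    cat(sprintf("  %-20s %d\n", s$category[i], s$count[i]))
})

#' Write a consistency report (TSV + JSON)
#'
#' @param report a [ConsistencyReport-class]
#' @param pathTSV per-AR rows output path
#' @param pathJSON optional JSON output (per-AR rows + summary block)
#' @return \code{pathTSV}, invisibly
#' @export
writeConsistencyReport <- function(report, pathTSV, pathJSON = NULL) {
  per <- report@perAR[order(report@perAR$ar_id), , drop = FALSE]
  write.table(per, pathTSV, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(pathJSON))
    jsonlite::write_json(list(per_ar = per, summary = report@summary),
                         pathJSON, dataframe = "rows", auto_unbox = TRUE,
                         pretty = TRUE)
  invisible(pathTSV)
}

## rebuild an AtomicRegulonSet after member removal, preserving consensus
## profiles and tabulated counts of the surviving ARs
.subsetARs <- function(ars, membership) {
  ids <- sort(unique(membership$ar_id))
  old <- as.character(rownames(ars@consensus))
  sel <- match(as.character(ids), old)
  AtomicRegulonSet(membership,
                   consensus = ars@consensus[sel, , drop = FALSE],
                   onCount = ars@onCount[sel], offCount = ars@offCount[sel],
                   unplaced = ars@unplaced,
                   labels = ars@labels[sel])
}

#' @describeIn stripRegulators removal of regulator-encoding member genes
#' @export
setMethod("stripRegulators",
          signature("AtomicRegulonSet", "RegulatoryNetwork"),
          function(ars, net, minSize = 2L) {
  reg <- regulators(net)
  regGenes <- unique(reg$encoding_gene[!is.na(reg$encoding_gene)])
  mb <- ars@membership
  hit <- mb$locus_tag %in% regGenes
  log <- data.frame(action = rep("remove_regulator", sum(hit)),
                    ar_id = mb$ar_id[hit], gene = mb$locus_tag[hit],
                    reason = rep("encodes a network regulator", sum(hit)),
                    stringsAsFactors = FALSE)
  mb2 <- mb[!hit, , drop = FALSE]
  sz <- table(mb2$ar_id)
  flagged <- as.integer(names(sz)[sz < minSize])
  flagged <- unique(c(flagged, setdiff(mb$ar_id, mb2$ar_id)))
  out <- if (nrow(mb2)) .subsetARs(ars, mb2)
    else AtomicRegulonSet(mb2, unplaced = ars@unplaced)
  list(ars = out, log = log, flagged = sort(flagged))
})

#' @describeIn dropDiscordantMembers removal of minority-signature members
#' @export
setMethod("dropDiscordantMembers",
          signature("AtomicRegulonSet", "RegulatoryNetwork"),
          function(ars, net, minSize = 2L) {
  gsets <- arGenes(ars)
  mb <- ars@membership
  drop <- character()
  logs <- list()
  for (nm in names(gsets)) {
    genes <- mb$locus_tag[mb$ar_id == as.integer(nm)]  # membership order
    cl <- .classifyGeneSet(genes, net)
    if (cl$category != "inconsistent") next
    keys <- vapply(cl$sigs, .signatureKey, character(1))
    nonEmpty <- keys[keys != ""]
    tab <- table(nonEmpty)
    ## keep the largest signature group; ties broken by earliest member
    best <- names(tab)[tab == max(tab)]
    if (length(best) > 1L) best <- nonEmpty[nonEmpty %in% best][1]
    bad <- names(keys)[keys != "" & keys != best]
    drop <- c(drop, bad)
    logs[[nm]] <- data.frame(action = "remove_discordant",
                             ar_id = as.integer(nm), gene = bad,
                             reason = "stimulus signature differs from AR majority",
                             stringsAsFactors = FALSE)
  }
  mb2 <- mb[!mb$locus_tag %in% drop, , drop = FALSE]
  sz <- table(mb2$ar_id)
  flagged <- as.integer(names(sz)[sz < minSize])
  out <- if (nrow(mb2)) .subsetARs(ars, mb2)
    else AtomicRegulonSet(mb2, unplaced = ars@unplaced)
  list(ars = out,
       log = if (length(logs)) do.call(rbind, c(logs, make.row.names = FALSE))
             else data.frame(action = character(), ar_id = integer(),
                             gene = character(), reason = character(),
                             stringsAsFactors = FALSE),
       flagged = sort(flagged))
})

#' @describeIn propagateStimuli proposals for one consistent-missing AR
#' @export
setMethod("propagateStimuli",
          signature("AtomicRegulonSet", "RegulatoryNetwork"),
          function(ars, net, arId) {
  genes <- arGenes(ars)[[as.character(arId)]]
  if (is.null(genes)) stop("no AR with id ", arId)
  cl <- .classifyGeneSet(genes, net)
  if (cl$category != "consistent_missing")
    stop("AR ", arId, " is classified '", cl$category,
         "'; stimulus propagation applies only to consistent_missing ARs")
  sigs <- cl$sigs
  nonEmpty <- sigs[vapply(sigs, nrow, integer(1)) > 0L]
  ## consensus signature: per stimulus, a known sign wins over unknown
  allsig <- do.call(rbind, nonEmpty)
  cons <- lapply(split(allsig$sign, allsig$stimulus_id), function(s) {
    s <- unique(s[!s %in% c("unknown", "conflict")])
    if (length(s) == 1L) s else "unknown"
  })
  consensusSig <- data.frame(stimulus_id = names(cons),
                             sign = unlist(cons, use.names = FALSE),
                             stringsAsFactors = FALSE)
  ## consensus regulator: unique regulator carrying these stimuli for members
  lnk <- links(net)
  lnk <- lnk[!is.na(lnk$stimulus_id) &
             lnk$stimulus_id %in% consensusSig$stimulus_id &
             lnk$target_gene %in% names(nonEmpty), , drop = FALSE]
  regs <- unique(lnk$regulator_id[!is.na(lnk$regulator_id)])
  regId <- if (length(regs) == 1L) regs else NA_character_
  emptyMembers <- setdiff(genes, names(nonEmpty))
  out <- expand.grid(target_gene = sort(emptyMembers),
                     stimulus_id = sort(consensusSig$stimulus_id),
                     stringsAsFactors = FALSE)
  out$sign <- setNames(consensusSig$sign,
                       consensusSig$stimulus_id)[out$stimulus_id]
  out$regulator_id <- regId
  out[c("regulator_id", "stimulus_id", "target_gene", "sign")]
})

.STOPWORDS <- c(
  "the", "a", "an", "of", "in", "at", "to", "and", "or", "was", "were",
  "with", "for", "is", "are", "on", "by", "after", "before", "during",
  "from", "into", "as", "its", "their"
)

#' Enrichment of sample metadata terms in an AR's ON samples
#'
#' Turns per-sample metadata into terms (the study id verbatim; lower-cased
#' description words minus stop-words; 2-grams of consecutive kept words) and
#' scores each term's overlap with the AR's ON-sample set by the one-sided
#' hypergeometric tail probability, with Benjamini-Hochberg q-values across
#' terms. This is the operator used to propose candidate stimuli for ARs with
#' no annotated effector (e.g. sporulation-study terms for an AR ON only late
#' after sporulation induction, or mitomycin C for prophage ARs).
#'
#' @param ars an [AtomicRegulonSet-class] with a consensus profile
#' @param bsm the [BinaryStateMatrix-class] the ARs were inferred from (its
#'   colData supplies \code{study_id} and \code{description})
#' @param arId id of the AR to score
#' @param qCutoff q-value cutoff used to flag the candidate-stimulus shortlist
#' @param stopwords words excluded from description terms
#' @return data.frame ranked by ascending p: \code{term}, \code{term_type}
#'   (\code{study} or \code{description}), \code{n_term} (samples carrying the
#'   term), \code{n_on}, \code{overlap}, \code{p}, \code{q},
#'   \code{candidate} (q <= qCutoff)
#' @export
enrichMetadata <- function(ars, bsm, arId, qCutoff = 0.05,
                           stopwords = .STOPWORDS) {
  cons <- consensusProfile(ars)
  if (!as.character(arId) %in% rownames(cons)) stop("no AR with id ", arId)
  prof <- cons[as.character(arId), ]
  onSamples <- colnames(cons)[!is.na(prof) & prof == 1L]
  if (!length(onSamples))
    stop("AR ", arId, " is never ON; nothing to enrich")
  cd <- SummarizedExperiment::colData(bsm)
  samples <- rownames(cd)
  n <- length(samples)
  termSets <- new.env(parent = emptyenv())
  addTerm <- function(term, type, sample) {
    key <- paste0(type, "\r", term)
    prev <- termSets[[key]]
    termSets[[key]] <- c(prev, sample)
  }
  for (i in seq_len(n)) {
    if (!is.na(cd$study_id[i]) && nzchar(cd$study_id[i]))
      addTerm(cd$study_id[i], "study", samples[i])
    d <- cd$description[i]
    if (is.na(d) || !nzchar(d)) next
    words <- strsplit(gsub("[^a-z0-9_]+", " ", tolower(d)), " +")[[1]]
    words <- words[nzchar(words) & !words %in% stopwords]
    for (w in unique(words)) addTerm(w, "description", samples[i])
    if (length(words) > 1L) {
      grams <- unique(paste(words[-length(words)], words[-1]))
      for (g in grams) addTerm(g, "description", samples[i])
    }
  }
  keys <- ls(termSets)
  if (!length(keys)) stop("no metadata terms available")
  k <- length(onSamples)
  rows <- lapply(keys, function(key) {
    parts <- strsplit(key, "\r", fixed = TRUE)[[1]]
    ts <- unique(termSets[[key]])
    m <- length(ts)
    ov <- length(intersect(ts, onSamples))
    data.frame(term = parts[2], term_type = parts[1], n_term = m, n_on = k,
               overlap = ov,
               p = phyper(ov - 1L, m, n - m, k, lower.tail = FALSE),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- p.adjust(out$p, method = "BH")
  ## rank: ascending p, study terms before description terms on ties, then
  ## larger overlap, then term
  typeOrder <- match(out$term_type, c("study", "description"))
  out <- out[order(out$p, typeOrder, -out$overlap, out$term), , drop = FALSE]
  rownames(out) <- NULL
  out$candidate <- out$q <= qCutoff
  out
}

#' Essential genes that are never expressed
#'
#' Intersects the always-OFF gene set with a list of essential genes. An empty
#' intersection is the expected, healthy outcome: a gene essential for growth
#' cannot be OFF in every condition.
#'
#' @param alwaysOffGenes locus tags called OFF in all samples
#' @param essential locus tags of essential genes
#' @return sorted character vector (ideally empty)
#' @export
essentialCheck <- function(alwaysOffGenes, essential) {
  sort(intersect(alwaysOffGenes, essential))
}

#' Read an essential-gene list
#'
#' @param path TSV whose first column holds locus tags (header optional,
#'   detected by a \code{locus_tag} first field)
#' @return character vector
#' @export
readEssentialGenes <- function(path) {
  if (!file.exists(path)) stop("essential-gene file not found: ", path)
  x <- read.delim(path, stringsAsFactors = FALSE, header = FALSE)[[1]]
  if (length(x) && x[1] == "locus_tag") x <- x[-1]
  unique(as.character(x))
}
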