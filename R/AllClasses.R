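#' @import methods
#' @importFrom stats cor median phyper p.adjust quantile rnorm runif setNames
#' @importFrom utils read.delim write.table head
NULL

## Closed mechanism taxonomy. Categories outside this list are accepted with an
## "other:" prefix so richer curated files parse losslessly.
.MECHANISM_CATEGORIES <- c(
  "TF", "TF+M", "TF+P", "TF+P+M", "TF+PP", "TF+PP+M", "TF+PTS", "TF+S",
  "TF+unk", "TF-TC",
  "P", "P-AT+M", "P-AT+PTS", "P-PTC",
  "SigmaFactor",
  "Riboswitch", "RNA-switch", "RNA-antiterminator", "sRNA", "antisenseRNA"
)

## Mechanisms that respond directly to a metabolic signal.
.METABOLIC_MECHANISMS <- c(
  "TF+M", "TF+PP+M", "TF+P+M", "P-AT+PTS", "P-AT+M", "Riboswitch"
)

.SIGNS <- c("induced", "repressed", "unknown")
.STIMULUS_CATEGORIES <- c("biochemical", "environmental")

#' Stimulus-annotated transcriptional regulatory network
#'
#' Container for a curated regulatory network: regulators (with their
#' regulatory mechanism category and the gene encoding them), stimuli
#' (effectors, biochemical or environmental), and links binding a regulator
#' and/or a stimulus to a target gene with an optional sign
#' (induced/repressed). Stimulons and per-gene stimulus signatures are derived
#' from the links.
#'
#' @slot regulators data.frame with columns \code{id}, \code{name},
#'   \code{encoding_gene} (locus tag or \code{NA}), \code{mechanism}.
#' @slot stimuli data.frame with columns \code{id}, \code{name},
#'   \code{category} (\code{"biochemical"} or \code{"environmental"}) and
#'   \code{characterized} (logical).
#' @slot links data.frame with columns \code{regulator_id} (or \code{NA}),
#'   \code{stimulus_id} (or \code{NA}), \code{target_gene}, \code{sign}
#'   (\code{"induced"}, \code{"repressed"}, \code{"unknown"}).
#' @slot genes character vector of locus tags known to the network.
#'
#' @seealso [readRegulatoryNetwork()], [deriveStimulons()], [networkSummary()]
#' @export
setClass("RegulatoryNetwork",
  representation(
    regulators = "data.frame",
    stimuli = "data.frame",
    links = "data.frame",
    genes = "character"
  )
)

setValidity("RegulatoryNetwork", function(object) {
  msg <- character()
  reg <- object@regulators
  sti <- object@stimuli
  lnk <- object@links
  need <- function(df, cols, what) {
    if (!all(cols %in% names(df)))
      msg <<- c(msg, sprintf("%s must have columns: %s", what,
                             paste(cols, collapse = ", ")))
  }
  need(reg, c("id", "name", "encoding_gene", "mechanism"), "regulators")
  need(sti, c("id", "name", "category", "characterized"), "stimuli")
  need(lnk, c("regulator_id", "stimulus_id", "target_gene", "sign"), "links")
  if (length(msg)) return(msg)

  if (anyDuplicated(reg$id)) msg <- c(msg, "duplicate regulator ids")
  if (anyDuplicated(sti$id)) msg <- c(msg, "duplicate stimulus ids")
  bad <- !.validMechanism(reg$mechanism)
  if (any(bad))
    msg <- c(msg, sprintf("unknown mechanism code(s): %s",
                          paste(unique(reg$mechanism[bad]), collapse = ", ")))
  if (!all(sti$category %in% .STIMULUS_CATEGORIES))
    msg <- c(msg, "stimulus category must be 'biochemical' or 'environmental'")
  if (nrow(lnk)) {
    if (any(is.na(lnk$regulator_id) & is.na(lnk$stimulus_id)))
      msg <- c(msg, "each link needs a regulator and/or a stimulus")
    if (!all(lnk$sign %in% .SIGNS))
      msg <- c(msg, "link sign must be induced/repressed/unknown")
    rid <- lnk$regulator_id[!is.na(lnk$regulator_id)]
    if (!all(rid %in% reg$id))
      msg <- c(msg, "link references undeclared regulator")
    sid <- lnk$stimulus_id[!is.na(lnk$stimulus_id)]
    if (!all(sid %in% sti$id))
      msg <- c(msg, "link references undeclared stimulus")
    if (!all(lnk$target_gene %in% object@genes))
      msg <- c(msg, "link references undeclared gene")
    key <- paste(lnk$stimulus_id, lnk$target_gene, lnk$sign, sep = "\r")
    key <- key[!is.na(lnk$stimulus_id)]
    if (anyDuplicated(key))
      msg <- c(msg, "duplicate (stimulus, target gene, sign) triples")
  }
  if (length(msg)) msg else TRUE
})

#' Binarized ON/OFF/UNCERTAIN call matrix
#'
#' A [SummarizedExperiment::SummarizedExperiment] whose single assay
#' \code{"calls"} holds per gene-sample calls encoded as integers:
#' \code{1L} = ON, \code{0L} = OFF, \code{NA} = UNCERTAIN.
#'
#' @seealso [binarizeExpression()], [calls()], [stateCounts()],
#'   [changedState()]
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @export
setClass("BinaryStateMatrix", contains = "SummarizedExperiment")

setValidity("BinaryStateMatrix", function(object) {
  if (!"calls" %in% SummarizedExperiment::assayNames(object))
    return("assay 'calls' is required")
  x <- SummarizedExperiment::assay(object, "calls")
  if (!is.integer(x)) return("calls must be an integer matrix (1/0/NA)")
  v <- x[!is.na(x)]
  if (length(v) && !all(v %in% c(0L, 1L)))
    return("calls must be 1 (ON), 0 (OFF) or NA (UNCERTAIN)")
  TRUE
})

#' Set of inferred Atomic Regulons
#'
#' An Atomic Regulon (AR) is a set of two or more genes with identical binary
#' ON/OFF expression profiles across all samples: in any sample the members
#' are either all ON or all OFF. This class holds a disjoint collection of
#' ARs: the gene membership with each member's average Pearson correlation to
#' its co-members, the per-sample consensus profile of each AR, the number of
#' samples each AR is ON and OFF, and the genes that could not be placed.
#'
#' @slot membership data.frame with columns \code{ar_id} (integer),
#'   \code{locus_tag}, \code{avg_pcc}.
#' @slot consensus integer matrix (ARs x samples; 1 = ON, 0 = OFF,
#'   NA = UNCERTAIN), rownames are AR ids. May have zero columns when an AR
#'   set is constructed from tabulated counts only.
#' @slot onCount,offCount integer vectors, per AR, of samples with a decided
#'   ON (resp. OFF) consensus call.
#' @slot unplaced character vector of genes not placed in any AR.
#' @slot labels character vector of optional per-AR labels (NA when unset).
#'
#' @seealso [inferAtomicRegulons()], [categorizeARs()], [classifyConsistency()]
#' @export
setClass("AtomicRegulonSet",
  representation(
    membership = "data.frame",
    consensus = "matrix",
    onCount = "integer",
    offCount = "integer",
    unplaced = "character",
    labels = "character"
  )
)

setValidity("AtomicRegulonSet", function(object) {
  msg <- character()
  mb <- object@membership
  if (!all(c("ar_id", "locus_tag", "avg_pcc") %in% names(mb)))
    return("membership must have columns ar_id, locus_tag, avg_pcc")
  if (anyDuplicated(mb$locus_tag))
    msg <- c(msg, "a gene may not belong to two ARs")
  ids <- sort(unique(mb$ar_id))
  if (nrow(object@consensus) && !identical(as.integer(rownames(object@consensus)), ids))
    msg <- c(msg, "consensus rownames must equal the sorted AR ids")
  k <- length(ids)
  if (length(object@onCount) != k || length(object@offCount) != k)
    msg <- c(msg, "onCount/offCount length must equal the number of ARs")
  if (length(object@labels) && length(object@labels) != k)
    msg <- c(msg, "labels length must equal the number of ARs")
  if (any(object@unplaced %in% mb$locus_tag))
    msg <- c(msg, "unplaced genes overlap AR members")
  if (length(msg)) msg else TRUE
})

#' Four-way AR/network consistency report
#'
#' Per-AR classification against a regulatory network into the four mutually
#' exclusive categories \code{consistent}, \code{consistent_missing}
#' (consistent with missing stimuli), \code{inconsistent} and \code{empty},
#' with a category summary whose counts sum to the number of ARs.
#'
#' @slot perAR data.frame with columns \code{ar_id}, \code{category},
#'   \code{n_members}, \code{n_empty}, \code{n_signatures}.
#' @slot summary data.frame with columns \code{category} and \code{count}.
#' @slot witnesses list (per AR id, as character names) of the member
#'   signatures involved in the classification.
#'
#' @seealso [consistencyReport()], [classifyConsistency()]
#' @export
setClass("ConsistencyReport",
  representation(
    perAR = "data.frame",
    summary = "data.frame",
    witnesses = "list"
  )
)

setValidity("ConsistencyReport", function(object) {
  cats <- c("consistent", "consistent_missing", "inconsistent", "empty")
  if (!all(object@perAR$category %in% cats))
    return("unknown consistency category")
  if (sum(object@summary$count) != nrow(object@perAR))
    return("summary counts must sum to the number of ARs")
  TRUE
})
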