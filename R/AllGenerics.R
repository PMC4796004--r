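#' @rdname RegulatoryNetwork-class
#' @param x,object a \code{RegulatoryNetwork}
#' @export
setGeneric("regulators", function(x) standardGeneric("regulators"))

#' @rdname RegulatoryNetwork-class
#' @export
setGeneric("stimuli", function(x) standardGeneric("stimuli"))

#' @rdname RegulatoryNetwork-class
#' @export
setGeneric("links", function(x) standardGeneric("links"))

#' @rdname RegulatoryNetwork-class
#' @export
setGeneric("networkGenes", function(x) standardGeneric("networkGenes"))

#' Derive stimulons from a regulatory network
#'
#' A stimulon is the set of genes responding to one stimulus. A gene belongs
#' to the stimulon of stimulus \code{s} exactly when a link (\code{s}, gene)
#' exists; genes may belong to many stimulons.
#'
#' @param net a [RegulatoryNetwork-class]
#' @return named list mapping stimulus id to a character vector of locus tags
#'   (sorted, unique). Stimuli with no links are omitted.
#' @export
setGeneric("deriveStimulons", function(net) standardGeneric("deriveStimulons"))

#' Summary statistics of a regulatory network
#'
#' Census of the network: regulators per mechanism category, regulator-class
#' totals (transcription factors, sigma factors, RNA-level regulators,
#' other protein-level regulators), number of effectors, number of distinct
#' regulated genes, and genes per mechanism (a gene is counted once per
#' distinct mechanism controlling it).
#'
#' @param net a [RegulatoryNetwork-class]
#' @return a list with elements \code{regulators_by_mechanism} (named integer),
#'   \code{classes} (named integer: tf, sigma_factor, rna, protein, other),
#'   \code{n_regulators}, \code{n_effectors}, \code{n_regulated_genes},
#'   \code{genes_by_mechanism} (named integer).
#' @export
setGeneric("networkSummary", function(net) standardGeneric("networkSummary"))

#' @rdname BinaryStateMatrix-class
#' @param x a \code{BinaryStateMatrix}
#' @export
setGeneric("calls", function(x) standardGeneric("calls"))

#' Per-gene ON/OFF/UNCERTAIN sample counts
#'
#' @param x a [BinaryStateMatrix-class]
#' @return data.frame with columns \code{locus_tag}, \code{on}, \code{off},
#'   \code{uncertain}; the three counts sum to the number of samples.
#' @export
setGeneric("stateCounts", function(x) standardGeneric("stateCounts"))

#' Genes that changed state between two samples
#'
#' Returns the genes whose calls are decided (non-UNCERTAIN) in both samples
#' and differ. Symmetric in its sample arguments. This is the query used to
#' find, e.g., prophage genes switching ON between an untreated control and a
#' mitomycin C treated sample.
#'
#' @param x a [BinaryStateMatrix-class]
#' @param sampleA,sampleB sample identifiers (column names)
#' @return character vector of locus tags
#' @export
setGeneric("changedState",
           function(x, sampleA, sampleB) standardGeneric("changedState"))

#' @rdname AtomicRegulonSet-class
#' @param x,object an \code{AtomicRegulonSet}
#' @export
setGeneric("arIds", function(x) standardGeneric("arIds"))

#' @rdname AtomicRegulonSet-class
#' @export
setGeneric("arGenes", function(x) standardGeneric("arGenes"))

#' @rdname AtomicRegulonSet-class
#' @export
setGeneric("arMembership", function(x) standardGeneric("arMembership"))

#' @rdname AtomicRegulonSet-class
#' @export
setGeneric("consensusProfile", function(x) standardGeneric("consensusProfile"))

#' @rdname AtomicRegulonSet-class
#' @export
setGeneric("onCount", function(x) standardGeneric("onCount"))

#' @rdname AtomicRegulonSet-class
#' @export
setGeneric("offCount", function(x) standardGeneric("offCount"))

#' @rdname AtomicRegulonSet-class
#' @export
setGeneric("unplaced", function(x) standardGeneric("unplaced"))

#' Categorize ARs by expression profile
#'
#' An AR is always-ON when its consensus profile is never OFF and at least
#' once ON, always-OFF symmetrically, and differentially expressed otherwise.
#'
#' @param ars an [AtomicRegulonSet-class]
#' @return list with character-id vectors \code{always_on}, \code{always_off},
#'   \code{differential}, and \code{gene_counts}, a named integer rollup of
#'   member genes per category.
#' @export
setGeneric("categorizeARs", function(ars) standardGeneric("categorizeARs"))

#' Classify AR/network consistency
#'
#' Classifies each AR against the stimulus signatures its members carry in the
#' regulatory network: \code{empty} when no member has any stimulus,
#' \code{consistent} when all members have equal non-empty signatures,
#' \code{consistent_missing} when the non-empty signatures agree but at least
#' one member has none, and \code{inconsistent} when two members carry
#' different non-empty signatures. Sign agreement is required only when both
#' links carry a known sign.
#'
#' @param ars an [AtomicRegulonSet-class]
#' @param net a [RegulatoryNetwork-class]
#' @return named character vector of categories, one per AR id
#' @export
setGeneric("classifyConsistency",
           function(ars, net) standardGeneric("classifyConsistency"))

#' Full consistency report
#'
#' @inheritParams classifyConsistency
#' @return a [ConsistencyReport-class]
#' @export
setGeneric("consistencyReport",
           function(ars, net) standardGeneric("consistencyReport"))

#' Remove regulator-encoding genes from ARs
#'
#' ARs frequently capture a regulator together with its targets; for use as
#' regulons in a network model the regulator gene itself is removed. Any AR
#' falling below \code{minSize} members is flagged in the log, never silently
#' deleted.
#'
#' @param ars an [AtomicRegulonSet-class]
#' @param net a [RegulatoryNetwork-class]
#' @param minSize flag ARs left with fewer members than this
#' @return list with \code{ars} (updated set), \code{log} (data.frame:
#'   action, ar_id, gene, reason) and \code{flagged} (AR ids below minSize)
#' @export
setGeneric("stripRegulators",
           function(ars, net, minSize = 2L) standardGeneric("stripRegulators"))

#' Remove discordant members from inconsistent ARs
#'
#' For each inconsistent AR, keeps the largest group of members sharing one
#' stimulus signature (plus members with no signature) and removes the
#' minority members, logging every removal. Re-classification after this
#' curation never worsens an AR's category.
#'
#' @inheritParams stripRegulators
#' @return list with \code{ars}, \code{log} and \code{flagged}, as
#'   [stripRegulators()]
#' @export
setGeneric("dropDiscordantMembers",
           function(ars, net, minSize = 2L)
             standardGeneric("dropDiscordantMembers"))

#' Propose stimulus links for members with missing stimuli
#'
#' For an AR classified consistent-with-missing-stimuli, proposes new
#' regulatory links for every member with an empty signature, copying the
#' consensus signature of the annotated members (and the consensus regulator
#' when it is unique). Proposals only; the network is not modified.
#'
#' @param ars an [AtomicRegulonSet-class]
#' @param net a [RegulatoryNetwork-class]
#' @param arId id of one AR in \code{ars}
#' @return data.frame of proposed links: \code{regulator_id},
#'   \code{stimulus_id}, \code{target_gene}, \code{sign}
#' @export
setGeneric("propagateStimuli",
           function(ars, net, arId) standardGeneric("propagateStimuli"))
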