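## Regulatory network data model and I/O.

.validMechanism <- function(m) {
  m %in% .MECHANISM_CATEGORIES | grepl("^other:.+", m)
}

#' Mechanism categories of the regulatory model
#'
#' The closed taxonomy of regulatory mechanism codes (transcription factors
#' plain or conditioned by metabolites, accessory/phosphorylated proteins, PTS
#' phosphorylation or stress; sigma factors; protein-level antiterminators and
#' post-transcriptional control; and RNA-level regulators: riboswitches, RNA
#' switches, RNA antiterminators, small RNAs and antisense RNAs). Codes outside
#' the taxonomy are carried with an \code{"other:"} prefix.
#'
#' @return character vector of mechanism codes
#' @export
mechanismCategories <- function() .MECHANISM_CATEGORIES

#' Does a mechanism respond directly to a metabolic signal?
#'
#' TRUE exactly for the mechanism classes driven by a metabolite: TF+M,
#' TF+PP+M, TF+P+M, P-AT+PTS, P-AT+M and Riboswitch.
#'
#' @param mechanism character vector of mechanism codes
#' @return logical vector
#' @export
respondsToMetabolite <- function(mechanism) {
  mechanism %in% .METABOLIC_MECHANISMS
}

## Canonical stimulus id: case-folded, runs of whitespace/underscores
## collapsed to single underscores ("Disulfide_stress conditions" ->
## "disulfide_stress_conditions").
.canonicalStimulus <- function(x) {
  x <- tolower(trimws(x))
  gsub("[[:space:]_]+", "_", x)
}

#' Construct a RegulatoryNetwork
#'
#' Low-level constructor; most users will call [readRegulatoryNetwork()].
#' Stimulus ids are canonicalized (case-folded, whitespace/underscore runs
#' collapsed).
#'
#' @param regulators data.frame(id, name, encoding_gene, mechanism)
#' @param stimuli data.frame(id, name, category, characterized)
#' @param links data.frame(regulator_id, stimulus_id, target_gene, sign)
#' @param genes character vector of locus tags; defaults to the link targets
#'   plus regulator-encoding genes
#' @return a [RegulatoryNetwork-class]
#' @export
RegulatoryNetwork <- function(regulators = NULL, stimuli = NULL, links = NULL,
                              genes = NULL) {
  empty_reg <- data.frame(id = character(), name = character(),
                          encoding_gene = character(), mechanism = character(),
                          stringsAsFactors = FALSE)
  empty_sti <- data.frame(id = character(), name = character(),
                          category = character(), characterized = logical(),
                          stringsAsFactors = FALSE)
  empty_lnk <- data.frame(regulator_id = character(), stimulus_id = character(),
                          target_gene = character(), sign = character(),
                          stringsAsFactors = FALSE)
  if (is.null(regulators)) regulators <- empty_reg
  if (is.null(stimuli)) stimuli <- empty_sti
  if (is.null(links)) links <- empty_lnk
  regulators <- as.data.frame(regulators, stringsAsFactors = FALSE)
  stimuli <- as.data.frame(stimuli, stringsAsFactors = FALSE)
  links <- as.data.frame(links, stringsAsFactors = FALSE)
  if (nrow(stimuli)) stimuli$id <- .canonicalStimulus(stimuli$id)
  if (nrow(links) && !is.null(links$stimulus_id)) {
    keep <- !is.na(links$stimulus_id)
    links$stimulus_id[keep] <- .canonicalStimulus(links$stimulus_id[keep])
  }
  if (nrow(links) && is.null(links$sign)) links$sign <- "unknown"
  if (nrow(links)) links$sign[is.na(links$sign) | links$sign == ""] <- "unknown"
  if (is.null(genes))
    genes <- unique(c(links$target_gene,
                      regulators$encoding_gene[!is.na(regulators$encoding_gene)]))
  rownames(regulators) <- rownames(stimuli) <- rownames(links) <- NULL
  new("RegulatoryNetwork", regulators = regulators, stimuli = stimuli,
      links = links, genes = as.character(genes))
}

#' Read a regulatory network from TSV
#'
#' Expects a UTF-8 TSV with a header and columns \code{regulator},
#' \code{mechanism}, \code{effector}, \code{effector_category}, \code{sign},
#' \code{target_gene}; an optional \code{regulator_gene} column gives the
#' locus tag encoding each regulator. Each row declares one
#' (regulator, effector, target) interaction; any of \code{regulator} or
#' \code{effector} may be blank, but not both. Effector names are
#' canonicalized; effectors named \code{uncharacterized} are identity-bearing:
#' an instance index (\code{uncharacterized-2}) is shared across rows, while a
#' bare \code{uncharacterized} receives a fresh unique id per row.
#'
#' @param path TSV file path
#' @return a validated [RegulatoryNetwork-class]
#' @export
readRegulatoryNetwork <- function(path) {
  if (!file.exists(path)) stop("network file not found: ", path)
  tab <- read.delim(path, stringsAsFactors = FALSE, na.strings = c("NA"),
                    check.names = FALSE, colClasses = "character")
  required <- c("regulator", "mechanism", "effector", "effector_category",
                "sign", "target_gene")
  missing <- setdiff(required, names(tab))
  if (length(missing))
    stop("network file ", path, " lacks column(s): ",
         paste(missing, collapse = ", "))
  n <- nrow(tab)
  blank <- function(x) is.na(x) | trimws(x) == "" | trimws(x) == "-"
  line <- seq_len(n) + 1L  # header is line 1

  reg_name <- trimws(tab$regulator)
  mech <- trimws(tab$mechanism)
  eff <- trimws(tab$effector)
  eff_cat <- trimws(tab$effector_category)
  sign <- trimws(tab$sign)
  target <- trimws(tab$target_gene)
  reg_gene <- if ("regulator_gene" %in% names(tab)) trimws(tab$regulator_gene)
              else rep(NA_character_, n)

  has_reg <- !blank(reg_name)
  has_eff <- !blank(eff)
  if (any(!has_reg & !has_eff))
    stop("line ", line[which(!has_reg & !has_eff)[1]],
         ": row has neither regulator nor effector")
  if (any(blank(target)))
    stop("line ", line[which(blank(target))[1]], ": missing target_gene")
  badmech <- has_reg & !blank(mech) & !.validMechanism(mech)
  if (any(badmech))
    stop("line ", line[which(badmech)[1]], ": unknown mechanism code '",
         mech[which(badmech)[1]], "'")

  sign[blank(sign)] <- "unknown"
  badsign <- !sign %in% .SIGNS
  if (any(badsign))
    stop("line ", line[which(badsign)[1]], ": invalid sign '",
         sign[which(badsign)[1]], "'")

  ## stimulus ids: canonical form; uncharacterized effectors keep per-instance
  ## identity, and a bare "uncharacterized" is a fresh instance per row
  stim_id <- ifelse(has_eff, .canonicalStimulus(eff), NA_character_)
  bare <- which(has_eff & stim_id %in% c("uncharacterized", "uncharacterised"))
  if (length(bare))
    stim_id[bare] <- sprintf("uncharacterized_auto%d", seq_along(bare))
  eff_cat[blank(eff_cat)] <- "biochemical"
  badcat <- has_eff & !eff_cat %in% .STIMULUS_CATEGORIES
  if (any(badcat))
    stop("line ", line[which(badcat)[1]], ": invalid effector_category '",
         eff_cat[which(badcat)[1]], "'")

  dupkey <- paste(stim_id, target, sign, sep = "\r")[has_eff]
  if (anyDuplicated(dupkey)) {
    i <- which(has_eff)[which(duplicated(dupkey))[1]]
    stop("line ", line[i], ": duplicate (stimulus, target_gene, sign) triple")
  }

  reg_rows <- which(has_reg & !duplicated(reg_name) & reg_name != "")
  regulators <- data.frame(
    id = reg_name[reg_rows],
    name = reg_name[reg_rows],
    encoding_gene = ifelse(blank(reg_gene[reg_rows]), NA_character_,
                           reg_gene[reg_rows]),
    mechanism = ifelse(blank(mech[reg_rows]), "other:unspecified",
                       mech[reg_rows]),
    stringsAsFactors = FALSE
  )
  sti_rows <- which(has_eff & !duplicated(stim_id))
  stimuli <- data.frame(
    id = stim_id[sti_rows],
    name = eff[sti_rows],
    category = eff_cat[sti_rows],
    characterized = !grepl("^uncharacteri", stim_id[sti_rows]),
    stringsAsFactors = FALSE
  )
  links <- data.frame(
    regulator_id = ifelse(has_reg, reg_name, NA_character_),
    stimulus_id = stim_id,
    target_gene = target,
    sign = sign,
    stringsAsFactors = FALSE
  )
  net <- RegulatoryNetwork(regulators, stimuli, links)
  validObject(net)
  net
}

#' Write a regulatory network to TSV
#'
#' Inverse of [readRegulatoryNetwork()]: a written network re-parses to an
#' identical object (stimulus ids are stored, so uncharacterized instances
#' keep their identity).
#'
#' @param net a [RegulatoryNetwork-class]
#' @param path output file path
#' @return \code{path}, invisibly
#' @export
writeRegulatoryNetwork <- function(net, path) {
  lnk <- links(net)
  reg <- regulators(net)
  sti <- stimuli(net)
  mech <- setNames(reg$mechanism, reg$id)
  rgene <- setNames(reg$encoding_gene, reg$id)
  cat_of <- setNames(sti$category, sti$id)
  ## emit the original name for characterized stimuli (re-parsing
  ## canonicalizes back to the same id); uncharacterized instances keep
  ## their identity-bearing id
  nameOf <- setNames(ifelse(sti$characterized, sti$name, sti$id), sti$id)
  out <- data.frame(
    regulator = ifelse(is.na(lnk$regulator_id), "", lnk$regulator_id),
    regulator_gene = ifelse(is.na(lnk$regulator_id), "",
                            ifelse(is.na(rgene[lnk$regulator_id]), "",
                                   rgene[lnk$regulator_id])),
    mechanism = ifelse(is.na(lnk$regulator_id), "", mech[lnk$regulator_id]),
    effector = ifelse(is.na(lnk$stimulus_id), "", nameOf[lnk$stimulus_id]),
    effector_category = ifelse(is.na(lnk$stimulus_id), "",
                               cat_of[lnk$stimulus_id]),
    sign = lnk$sign,
    target_gene = lnk$target_gene,
    stringsAsFactors = FALSE
  )
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Export a regulatory network as JSON
#'
#' @param net a [RegulatoryNetwork-class]
#' @param path output file path
#' @return \code{path}, invisibly
#' @export
exportNetworkJSON <- function(net, path) {
  jsonlite::write_json(
    list(regulators = regulators(net), stimuli = stimuli(net),
         links = links(net), genes = networkGenes(net)),
    path, dataframe = "rows", na = "null", auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname RegulatoryNetwork-class
#' @export
setMethod("regulators", "RegulatoryNetwork", function(x) x@regulators)

#' @rdname RegulatoryNetwork-class
#' @export
setMethod("stimuli", "RegulatoryNetwork", function(x) x@stimuli)

#' @rdname RegulatoryNetwork-class
#' @export
setMethod("links", "RegulatoryNetwork", function(x) x@links)

#' @rdname RegulatoryNetwork-class
#' @export
setMethod("networkGenes", "RegulatoryNetwork", function(x) x@genes)

#' @describeIn deriveStimulons gene sets per stimulus
#' @export
setMethod("deriveStimulons", "RegulatoryNetwork", function(net) {
  lnk <- links(net)
  lnk <- lnk[!is.na(lnk$stimulus_id), , drop = FALSE]
  if (!nrow(lnk)) return(setNames(list(), character()))
  sp <- split(lnk$target_gene, lnk$stimulus_id)
  lapply(sp[sort(names(sp))], function(g) sort(unique(g)))
})

.mechanismClass <- function(mech) {
  ifelse(mech == "SigmaFactor", "sigma_factor",
  ifelse(mech %in% c("Riboswitch", "RNA-switch", "RNA-antiterminator",
                     "sRNA", "antisenseRNA"), "rna",
  ifelse(grepl("^TF", mech), "tf",
  ifelse(mech %in% c("P", "P-AT+M", "P-AT+PTS", "P-PTC"), "protein",
         "other"))))
}

#' @describeIn networkSummary network census
#' @export
setMethod("networkSummary", "RegulatoryNetwork", function(net) {
  reg <- regulators(net)
  lnk <- links(net)
  by_mech <- table(factor(reg$mechanism,
                          levels = sort(unique(reg$mechanism))))
  cls <- table(factor(.mechanismClass(reg$mechanism),
                      levels = c("tf", "sigma_factor", "rna", "protein",
                                 "other")))
  regulated <- unique(lnk$target_gene)
  ## genes per mechanism: one count per distinct (gene, mechanism) pair
  gm <- integer()
  if (nrow(lnk)) {
    wl <- lnk[!is.na(lnk$regulator_id), , drop = FALSE]
    if (nrow(wl)) {
      mech <- setNames(reg$mechanism, reg$id)[wl$regulator_id]
      pair <- unique(data.frame(gene = wl$target_gene, mech = mech,
                                stringsAsFactors = FALSE))
      gm_t <- table(factor(pair$mech, levels = sort(unique(pair$mech))))
      gm <- setNames(as.integer(gm_t), names(gm_t))
    }
  }
  list(
    regulators_by_mechanism = setNames(as.integer(by_mech), names(by_mech)),
    classes = setNames(as.integer(cls), names(cls)),
    n_regulators = nrow(reg),
    n_effectors = nrow(stimuli(net)),
    n_regulated_genes = length(regulated),
    genes_by_mechanism = gm
  )
})

#' @rdname RegulatoryNetwork-class
#' @export
setMethod("show", "RegulatoryNetwork", function(object) {
  cat("RegulatoryNetwork with", nrow(object@regulators), "regulators,",
      nrow(object@stimuli), "stimuli,", nrow(object@links), "links,",
      length(object@genes), "genes\n")
  cls <- networkSummary(object)$classes
  cat("  regulator classes:",
      paste(sprintf("%s=%d", names(cls), cls), collapse = ", "), "\n")
})

#' Write a network summary as TSV
#'
#' @param net a [RegulatoryNetwork-class]
#' @param path output file path
#' @return \code{path}, invisibly
#' @export
writeNetworkSummary <- function(net, path) {
  s <- networkSummary(net)
  rows <- rbind(
    data.frame(section = "class", key = names(s$classes),
               count = as.integer(s$classes), stringsAsFactors = FALSE),
    data.frame(section = "total",
               key = c("regulators", "effectors", "regulated_genes"),
               count = c(s$n_regulators, s$n_effectors, s$n_regulated_genes),
               stringsAsFactors = FALSE),
    data.frame(section = "regulators_by_mechanism",
               key = names(s$regulators_by_mechanism),
               count = as.integer(s$regulators_by_mechanism),
               stringsAsFactors = FALSE),
    if (length(s$genes_by_mechanism))
      data.frame(section = "genes_by_mechanism",
                 key = names(s$genes_by_mechanism),
                 count = as.integer(s$genes_by_mechanism),
                 stringsAsFactors = FALSE)
  )
  write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
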