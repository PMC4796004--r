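## End-to-end pipeline orchestration: configuration, subcommands, report
## assembly, provenance.

#' Read a run configuration
#'
#' A run configuration is a JSON object with a \code{seed}, an
#' \code{output_dir}, an \code{inputs} block (paths: \code{expression},
#' \code{metadata}, \code{features}, \code{subsystems}, \code{network},
#' \code{essential}; any may be omitted where a subcommand does not need it)
#' and optional parameter blocks \code{binarize} (\code{min_separation},
#' \code{uncertain_band}, \code{global_on_quantile}), \code{operons}
#' (\code{max_gap}), \code{infer} (\code{min_size}, \code{min_avg_pcc},
#' \code{min_codecided}) and \code{simulate} ([syntheticConfig()] fields).
#'
#' @param path JSON file
#' @return config list
#' @export
readRunConfig <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(cfg$seed)) cfg$seed <- 1L
  if (is.null(cfg$output_dir)) cfg$output_dir <- "."
  cfg
}

.cfgGet <- function(cfg, block, key, default) {
  v <- cfg[[block]][[key]]
  if (is.null(v)) default else v
}

.requireInput <- function(cfg, key) {
  p <- cfg$inputs[[key]]
  if (is.null(p)) stop("config lacks required input path: inputs$", key)
  if (!file.exists(p)) stop("input file not found: ", p)
  p
}

.loadExpression <- function(cfg) {
  p <- .requireInput(cfg, "expression")
  md <- cfg$inputs$metadata
  readExpressionMatrix(p, metadataPath = md,
                       log2Input = !isTRUE(cfg$inputs$linear_scale))
}

.binarizeStep <- function(cfg, se) {
  binarizeExpression(
    se,
    minSeparation = .cfgGet(cfg, "binarize", "min_separation", 1.0),
    uncertainBand = .cfgGet(cfg, "binarize", "uncertain_band", 0.5),
    globalOnQuantile = .cfgGet(cfg, "binarize", "global_on_quantile", 0.40))
}

.inferStep <- function(cfg, se, bsm) {
  features <- readGeneFeatures(.requireInput(cfg, "features"))
  subsystems <- if (!is.null(cfg$inputs$subsystems))
    readSubsystems(.requireInput(cfg, "subsystems")) else list()
  operons <- predictOperons(features,
                            maxGap = .cfgGet(cfg, "operons", "max_gap", 150L))
  drafts <- buildDraftRegulons(operons, subsystems)
  inferAtomicRegulons(
    drafts, bsm, se,
    minSize = .cfgGet(cfg, "infer", "min_size", 2L),
    minAvgPcc = .cfgGet(cfg, "infer", "min_avg_pcc", 0.6),
    minCodecided = .cfgGet(cfg, "infer", "min_codecided", 10L))
}

#' Run one pipeline subcommand
#'
#' Subcommands: \code{simulate} (generate a synthetic compendium into
#' \code{output_dir}), \code{binarize} (write \code{calls.tsv}),
#' \code{operons} (write \code{operons.tsv} and \code{drafts.tsv}),
#' \code{infer} (write \code{ars.tsv} and \code{unplaced.tsv}),
#' \code{reconcile} (write the consistency report, curation log and stimulus
#' proposals) and \code{report} (everything, plus the category breakdown,
#' network summary and a provenance record). All outputs are sorted
#' deterministically; two runs with the same config and seed produce identical
#' files. On error, files written by the failing run are removed.
#'
#' @param subcommand one of simulate, binarize, operons, infer, reconcile,
#'   report
#' @param config a config list or path to a JSON config ([readRunConfig()])
#' @return (invisibly) a list of the objects computed by the subcommand,
#'   including \code{files}, the paths written
#' @export
runPipeline <- function(subcommand = c("simulate", "binarize", "operons",
                                       "infer", "reconcile", "report"),
                        config) {
  subcommand <- match.arg(subcommand)
  cfg <- if (is.character(config)) readRunConfig(config) else config
  if (is.null(cfg$seed)) cfg$seed <- 1L
  if (is.null(cfg$output_dir)) cfg$output_dir <- "."
  dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(cfg$seed)
  written <- character()
  out <- function(name) {
    p <- file.path(cfg$output_dir, name)
    written <<- c(written, p)
    p
  }
  result <- tryCatch(
    .runSubcommand(subcommand, cfg, out),
    error = function(e) {
      unlink(written)
      stop(e)
    })
  result$files <- written
  invisible(result)
}

.runSubcommand <- function(subcommand, cfg, out) {
  if (subcommand == "simulate") {
    args <- cfg$simulate
    args$seed <- cfg$seed
    sim <- simulateCompendium(do.call(syntheticConfig, as.list(args)))
    writeCompendium(sim, cfg$output_dir)
    for (f in c("expression.tsv", "metadata.tsv", "features.gff3",
                "subsystems.tsv", "network.tsv", "config.json", "truth.json"))
      out(f)
    return(list(sim = sim))
  }

  se <- .loadExpression(cfg)
  bsm <- .binarizeStep(cfg, se)
  if (subcommand == "binarize") {
    writeCalls(bsm, out("calls.tsv"))
    return(list(calls = bsm))
  }

  if (subcommand == "operons") {
    features <- readGeneFeatures(.requireInput(cfg, "features"))
    operons <- predictOperons(features,
                              maxGap = .cfgGet(cfg, "operons", "max_gap",
                                               150L))
    opTab <- data.frame(operon_id = rep(names(operons), lengths(operons)),
                        locus_tag = unlist(operons, use.names = FALSE),
                        stringsAsFactors = FALSE)
    write.table(opTab, out("operons.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    subsystems <- if (!is.null(cfg$inputs$subsystems))
      readSubsystems(.requireInput(cfg, "subsystems")) else list()
    drafts <- buildDraftRegulons(operons, subsystems)
    drTab <- data.frame(
      draft_id = rep(names(drafts), vapply(drafts, function(d)
        length(d$genes), integer(1))),
      locus_tag = unlist(lapply(drafts, `[[`, "genes"), use.names = FALSE),
      stringsAsFactors = FALSE)
    write.table(drTab, out("drafts.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    return(list(operons = operons, drafts = drafts))
  }

  ars <- .inferStep(cfg, se, bsm)
  features <- readGeneFeatures(.requireInput(cfg, "features"))
  if (subcommand == "infer") {
    writeAtomicRegulons(ars, out("ars.tsv"), features = features)
    writeLines(sort(unplaced(ars)), out("unplaced.tsv"))
    return(list(ars = ars, calls = bsm))
  }

  net <- readRegulatoryNetwork(.requireInput(cfg, "network"))
  reportV1 <- consistencyReport(ars, net)
  strip <- stripRegulators(ars, net)
  curated <- dropDiscordantMembers(strip$ars, net)
  reportV2 <- consistencyReport(curated$ars, net)
  curationLog <- rbind(strip$log, curated$log)

  perV2 <- reportV2@perAR
  cmARs <- perV2$ar_id[perV2$category == "consistent_missing"]
  proposals <- if (length(cmARs))
    do.call(rbind, lapply(cmARs, function(id)
      propagateStimuli(curated$ars, net, id)))
  else data.frame(regulator_id = character(), stimulus_id = character(),
                  target_gene = character(), sign = character(),
                  stringsAsFactors = FALSE)

  if (subcommand == "reconcile") {
    writeConsistencyReport(reportV1, out("consistency_per_ar.tsv"))
    writeCurationAndProposals(curationLog, proposals, reportV1, reportV2,
                              out)
    return(list(ars = ars, curated = curated$ars, reportV1 = reportV1,
                reportV2 = reportV2, proposals = proposals,
                curationLog = curationLog))
  }

  ## report: full assembly
  writeAtomicRegulons(ars, out("ars.tsv"), features = features)
  writeLines(sort(unplaced(ars)), out("unplaced.tsv"))
  cats <- categorizeARs(ars)
  catTab <- data.frame(
    category = c("always_on", "always_off", "differential"),
    n_ars = c(length(cats$always_on), length(cats$always_off),
              length(cats$differential)),
    n_genes = as.integer(cats$gene_counts),
    stringsAsFactors = FALSE)
  write.table(catTab, out("category_breakdown.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  writeNetworkSummary(net, out("network_summary.tsv"))
  writeConsistencyReport(reportV1, out("consistency_per_ar.tsv"))
  writeCurationAndProposals(curationLog, proposals, reportV1, reportV2, out)

  essential <- character()
  if (!is.null(cfg$inputs$essential)) {
    essential <- readEssentialGenes(.requireInput(cfg, "essential"))
    offGenes <- ars@membership$locus_tag[
      ars@membership$ar_id %in% as.integer(cats$always_off)]
    writeLines(essentialCheck(offGenes, essential),
               out("essential_off_genes.tsv"))
  }

  cfgFile <- tempfile(fileext = ".json")
  jsonlite::write_json(cfg, cfgFile, auto_unbox = TRUE, force = TRUE)
  prov <- list(
    config_md5 = unname(tools::md5sum(cfgFile)),
    seed = cfg$seed,
    package_version = as.character(utils::packageVersion("AtomicRegulons")),
    r_version = paste(R.version$major, R.version$minor, sep = "."))
  unlink(cfgFile)
  jsonlite::write_json(prov, out("provenance.json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(list(ars = ars, calls = bsm, reportV1 = reportV1,
                 reportV2 = reportV2, proposals = proposals,
                 curationLog = curationLog, categories = cats))
}

## shared between reconcile and report
writeCurationAndProposals <- function(curationLog, proposals, reportV1,
                                      reportV2, out) {
  cl <- curationLog[order(curationLog$ar_id, curationLog$gene), ,
                    drop = FALSE]
  write.table(cl, out("curation_log.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  pr <- proposals[order(proposals$target_gene, proposals$stimulus_id), ,
                  drop = FALSE]
  write.table(pr, out("proposals.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE, na = "")
  sm <- merge(reportV1@summary, reportV2@summary, by = "category",
              sort = FALSE, suffixes = c("_V1", "_V2"))
  names(sm) <- c("category", "count_V1", "count_V2")
  sm <- rbind(sm, data.frame(category = "total",
                             count_V1 = sum(sm$count_V1),
                             count_V2 = sum(sm$count_V2)))
  write.table(sm, out("consistency_summary.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(NULL)
}

#' Read an AR table written by [writeAtomicRegulons()]
#'
#' Reconstructs an [AtomicRegulonSet-class] from the tabulated form (counts
#' only; no per-sample consensus profile).
#'
#' @param path TSV path
#' @return an [AtomicRegulonSet-class]
#' @export
readAtomicRegulons <- function(path) {
  if (!file.exists(path)) stop("AR table not found: ", path)
  tab <- read.delim(path, stringsAsFactors = FALSE)
  ids <- sort(unique(tab$ar_id))
  first <- tab[match(ids, tab$ar_id), , drop = FALSE]
  AtomicRegulonSet(
    tab[c("ar_id", "locus_tag", "avg_pcc")],
    onCount = as.integer(first$on_count),
    offCount = as.integer(first$off_count),
    labels = as.character(first$label))
}
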