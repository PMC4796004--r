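## Synthetic benchmark generator: ground-truth regulatory network, operon
## layout, condition design, and bimodal expression compendium.

.BIOCHEM_NAMES <- c(
  "glucose", "sucrose", "xylose", "malate", "ribose", "glycerol",
  "trehalose", "arginine", "glutamine", "citrate", "gluconate", "maltose",
  "iron", "zinc", "manganese", "phosphate", "nitrate", "ammonium"
)
.ENVIRON_NAMES <- c(
  "heat_shock", "cold_shock", "salt_stress", "oxidative_stress",
  "dna_damage", "acid_stress", "ethanol_stress", "anaerobiosis",
  "stationary_phase", "sporulation_signal", "biofilm_signal", "phage_stress"
)

#' Configuration for the synthetic compendium generator
#'
#' Defaults describe the benchmark the package is validated on: a 4000-gene
#' genome carrying 50 planted ARs (each spanning 1-3 operons tied together by
#' a subsystem and wired to 1-3 stimuli), 17% always-ON and 4% always-OFF
#' genes, and a 120-sample compendium grouped into studies whose sample
#' descriptions name the stimuli active in each sample. Expression is a
#' two-level model, \code{offLevel + (onLevel - offLevel) * state +
#' N(0, noiseSd)} in log2 units; the default noise is 15% of the ON-OFF
#' separation.
#'
#' @param nGenes,nArs,nSamples,nStudies,nStimuli design sizes
#' @param fracAlwaysOn,fracAlwaysOff fractions of genes constitutively ON/OFF
#' @param onLevel,offLevel log2 expression of the two states
#' @param noiseSd Gaussian noise (log2 units); default 0.15 * (on - off)
#' @param fracRepressed fraction of planted ARs wired with repression (most
#'   curated stimulus annotations record induction)
#' @param meanOperonLen,gapBp,interOperonGapBp,geneLenBp operon geometry
#' @param seed RNG seed; the full output is reproducible from it
#' @return validated config list (class \code{SyntheticConfig})
#' @export
syntheticConfig <- function(nGenes = 4000L, nArs = 50L, nSamples = 120L,
                            nStudies = 24L, nStimuli = 60L,
                            fracAlwaysOn = 0.17, fracAlwaysOff = 0.04,
                            onLevel = 9, offLevel = 6,
                            noiseSd = 0.15 * (onLevel - offLevel),
                            fracRepressed = 0.05,
                            meanOperonLen = 3L, gapBp = 80L,
                            interOperonGapBp = 500L, geneLenBp = 900L,
                            seed = 1L) {
  cfg <- list(nGenes = as.integer(nGenes), nArs = as.integer(nArs),
              nSamples = as.integer(nSamples), nStudies = as.integer(nStudies),
              nStimuli = as.integer(nStimuli), fracAlwaysOn = fracAlwaysOn,
              fracAlwaysOff = fracAlwaysOff, onLevel = onLevel,
              offLevel = offLevel, noiseSd = noiseSd,
              fracRepressed = fracRepressed,
              meanOperonLen = as.integer(meanOperonLen),
              gapBp = as.integer(gapBp),
              interOperonGapBp = as.integer(interOperonGapBp),
              geneLenBp = as.integer(geneLenBp), seed = as.integer(seed))
  if (cfg$fracAlwaysOn < 0 || cfg$fracAlwaysOff < 0 ||
      cfg$fracAlwaysOn + cfg$fracAlwaysOff >= 1)
    stop("always-ON/OFF fractions must be in [0,1) and sum below 1")
  if (cfg$onLevel <= cfg$offLevel) stop("onLevel must exceed offLevel")
  if (cfg$noiseSd < 0) stop("noiseSd must be non-negative")
  if (cfg$nSamples < 2L) stop("need at least 2 samples")
  if (cfg$nStudies > cfg$nSamples) stop("more studies than samples")
  if (cfg$nArs * 2L > cfg$nGenes * (1 - cfg$fracAlwaysOn - cfg$fracAlwaysOff))
    stop("infeasible config: planted ARs require more genes than available")
  structure(cfg, class = "SyntheticConfig")
}

.stimulusNames <- function(n) {
  base <- c(.BIOCHEM_NAMES, .ENVIRON_NAMES)
  cat <- c(rep("biochemical", length(.BIOCHEM_NAMES)),
           rep("environmental", length(.ENVIRON_NAMES)))
  reps <- ceiling(n / length(base))
  nm <- paste0(rep(base, reps), "_", rep(seq_len(reps), each = length(base)))
  data.frame(name = nm[seq_len(n)], category = rep(cat, reps)[seq_len(n)],
             stringsAsFactors = FALSE)
}

#' Generate a synthetic compendium with ground truth
#'
#' Produces, fully reproducibly from \code{config$seed}, all inputs the AR
#' pipeline consumes plus the planted truth: gene features laid out in
#' operons, subsystems tying each planted AR's operons together, the true
#' stimulus-annotated regulatory network, per-sample stimulus states grouped
#' into studies (sample descriptions name the active stimuli, so metadata
#' enrichment can recover them), the planted ON/OFF call matrix, and the noisy
#' continuous expression matrix. Genes outside planted ARs are constitutively
#' ON, constitutively OFF, or idiosyncratic "noise" genes with their own
#' random profile.
#'
#' @param config a [syntheticConfig()]
#' @return list with elements \code{features} (GRanges), \code{subsystems},
#'   \code{network} ([RegulatoryNetwork-class]), \code{expression}
#'   (SummarizedExperiment), \code{truth} (list: \code{arAssignments} named
#'   integer vector over planted genes, \code{ars}, \code{alwaysOn},
#'   \code{alwaysOff}, \code{background}, \code{stimulusStates},
#'   \code{plantedCalls}, \code{arStimuli}, \code{arSigns}) and \code{config}
#' @export
simulateCompendium <- function(config = syntheticConfig()) {
  stopifnot(inherits(config, "SyntheticConfig"))
  if (exists(".Random.seed", envir = globalenv())) {
    oldSeed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", oldSeed, envir = globalenv()), add = TRUE)
  }
  set.seed(config$seed)

  nG <- config$nGenes
  nS <- config$nSamples

  ## --- operon plan: roles "ar<k>", "on", "off", "bg"
  opLens <- integer()
  opRoles <- character()
  for (k in seq_len(config$nArs)) {
    nOp <- sample(1:3, 1)
    lens <- sample(2:4, nOp, replace = TRUE)
    opLens <- c(opLens, lens)
    opRoles <- c(opRoles, rep(paste0("ar", k), nOp))
  }
  nArGenes <- sum(opLens)
  nOn <- round(config$fracAlwaysOn * nG)
  nOff <- round(config$fracAlwaysOff * nG)
  if (nArGenes + nOn + nOff > nG)
    stop("infeasible config: planted ARs require more genes than available")
  fillBlock <- function(count, role, lo, hi) {
    lens <- integer()
    while (sum(lens) < count) lens <- c(lens, sample(lo:hi, 1))
    if (sum(lens) > count) {
      excess <- sum(lens) - count
      lens[length(lens)] <- lens[length(lens)] - excess
      if (lens[length(lens)] < 1L) lens <- lens[-length(lens)]
    }
    list(lens = lens, roles = rep(role, length(lens)))
  }
  onB <- fillBlock(nOn, "on", 2, 4)
  offB <- fillBlock(nOff, "off", 2, 4)
  bgB <- fillBlock(nG - nArGenes - sum(onB$lens) - sum(offB$lens), "bg", 1, 4)
  opLens <- c(opLens, onB$lens, offB$lens, bgB$lens)
  opRoles <- c(opRoles, onB$roles, offB$roles, bgB$roles)
  ord <- sample(length(opLens))
  opLens <- opLens[ord]
  opRoles <- opRoles[ord]
  nGtot <- sum(opLens)

  ## --- genome layout
  tags <- sprintf("SYN_%05d", seq_len(nGtot))
  geneRole <- rep(opRoles, opLens)
  geneOp <- rep(seq_along(opLens), opLens)
  starts <- integer(nGtot)
  pos <- 1L
  for (i in seq_len(nGtot)) {
    starts[i] <- pos
    sameOp <- i < nGtot && geneOp[i + 1L] == geneOp[i]
    pos <- pos + config$geneLenBp +
      (if (sameOp) config$gapBp else config$interOperonGapBp)
  }
  strandOfOp <- sample(c("+", "-"), length(opLens), replace = TRUE)
  features <- GenomicRanges::GRanges(
    seqnames = "chr",
    ranges = IRanges::IRanges(start = starts,
                              end = starts + config$geneLenBp - 1L),
    strand = strandOfOp[geneOp],
    locus_tag = tags,
    name = tags,
    product = ifelse(geneRole == "bg", "hypothetical protein",
                     paste0("synthetic ", geneRole, " protein")))

  ## --- subsystems: one per planted AR, tying its operons together
  subsystems <- list()
  for (k in seq_len(config$nArs)) {
    g <- tags[geneRole == paste0("ar", k)]
    subsystems[[sprintf("subsystem_ar%02d", k)]] <- g
  }

  ## --- studies and samples
  studyOf <- sort(rep_len(seq_len(config$nStudies), nS))
  sampleIds <- sprintf("S%03d", seq_len(nS))
  studyIds <- sprintf("study%04d", studyOf)

  ## --- stimuli: each lives in one home study, toggling within it
  sinfo <- .stimulusNames(config$nStimuli)
  homeStudy <- sample(config$nStudies, config$nStimuli, replace = TRUE)
  states <- matrix(0L, config$nStimuli, nS,
                   dimnames = list(sinfo$name, sampleIds))
  for (i in seq_len(config$nStimuli)) {
    idx <- which(studyOf == homeStudy[i])
    ## a stimulus is applied in >= 3 replicate samples of its home study
    ## (conditions are assayed in replicate) and absent in >= 1 control;
    ## two stimuli tested in the same study never share an activation pattern
    lo <- min(3L, length(idx) - 1L)
    prevPatterns <- apply(states[which(homeStudy[seq_len(i - 1L)] ==
                                       homeStudy[i]), idx, drop = FALSE],
                          1, paste, collapse = "")
    for (try in seq_len(200)) {
      nActive <- if (lo >= length(idx) - 1L) length(idx) - 1L
                 else sample(lo:(length(idx) - 1L), 1L)
      v <- integer(length(idx))
      v[sample(seq_along(idx), nActive)] <- 1L
      if (!paste(v, collapse = "") %in% prevPatterns) break
    }
    states[i, idx] <- v
  }

  ## --- wire each AR to 1-3 stimuli with a sign; profiles must be unique,
  ## distinct from constant, and signatures unique
  arStimuli <- vector("list", config$nArs)
  arSigns <- character(config$nArs)
  arProfile <- matrix(0L, config$nArs, nS)
  seenKeys <- character()
  for (k in seq_len(config$nArs)) {
    ok <- FALSE
    for (try in seq_len(500)) {
      ss <- sort(sample(config$nStimuli, sample(1:3, 1)))
      sgn <- if (runif(1) < config$fracRepressed) "repressed" else "induced"
      key <- paste(paste(ss, collapse = ","), sgn)
      prof <- as.integer(colSums(states[ss, , drop = FALSE]) > 0L)
      if (sgn == "repressed") prof <- 1L - prof
      if (key %in% seenKeys) next
      if (!any(prof == 1L) || !any(prof == 0L)) next
      if (k > 1L &&
          any(colSums(abs(t(arProfile[seq_len(k - 1L), , drop = FALSE]) -
                          prof)) == 0L)) next
      ok <- TRUE
      break
    }
    if (!ok) stop("could not wire AR ", k,
                  " to a unique stimulus combination; relax the config")
    seenKeys <- c(seenKeys, key)
    arStimuli[[k]] <- sinfo$name[ss]
    arSigns[k] <- sgn
    arProfile[k, ] <- prof
  }

  ## --- planted calls
  planted <- matrix(0L, nGtot, nS, dimnames = list(tags, sampleIds))
  for (k in seq_len(config$nArs))
    planted[geneRole == paste0("ar", k), ] <-
      rep(arProfile[k, ], each = sum(geneRole == paste0("ar", k)))
  planted[geneRole == "on", ] <- 1L
  bgGenes <- which(geneRole == "bg")
  for (i in bgGenes)
    planted[i, ] <- stats::rbinom(nS, 1L, runif(1, 0.2, 0.8))

  ## --- expression
  expr <- config$offLevel +
    (config$onLevel - config$offLevel) * planted +
    matrix(rnorm(nGtot * nS, 0, config$noiseSd), nGtot, nS)
  dimnames(expr) <- dimnames(planted)

  ## --- metadata: descriptions name the stimuli active in each sample
  descr <- vapply(seq_len(nS), function(j) {
    act <- rownames(states)[states[, j] == 1L]
    if (!length(act)) "control growth in rich medium"
    else paste0("tested gene expression after ",
                paste(act, collapse = " and "), " addition")
  }, character(1))
  cd <- S4Vectors::DataFrame(study_id = studyIds, description = descr,
                             row.names = sampleIds)
  se <- .newExpressionSE(expr, cd)

  ## --- true network
  regDf <- data.frame(
    id = sprintf("Reg%03d", seq_len(config$nArs)),
    name = sprintf("Reg%03d", seq_len(config$nArs)),
    encoding_gene = NA_character_,
    mechanism = sample(c("TF", "TF+M", "SigmaFactor", "Riboswitch", "TF-TC"),
                       config$nArs, replace = TRUE,
                       prob = c(0.35, 0.3, 0.15, 0.1, 0.1)),
    stringsAsFactors = FALSE)
  stiDf <- data.frame(id = sinfo$name, name = sinfo$name,
                      category = sinfo$category,
                      characterized = TRUE, stringsAsFactors = FALSE)
  linkRows <- list()
  for (k in seq_len(config$nArs)) {
    g <- tags[geneRole == paste0("ar", k)]
    linkRows[[k]] <- expand.grid(
      regulator_id = sprintf("Reg%03d", k),
      stimulus_id = arStimuli[[k]], target_gene = g,
      stringsAsFactors = FALSE)
    linkRows[[k]]$sign <- arSigns[k]
  }
  linkDf <- do.call(rbind, linkRows)
  net <- RegulatoryNetwork(regDf, stiDf, linkDf, genes = tags)
  validObject(net)

  arAssign <- setNames(
    as.integer(sub("^ar", "", geneRole[grepl("^ar", geneRole)])),
    tags[grepl("^ar", geneRole)])
  truth <- list(
    arAssignments = arAssign,
    ars = split(names(arAssign), arAssign),
    alwaysOn = tags[geneRole == "on"],
    alwaysOff = tags[geneRole == "off"],
    background = tags[geneRole == "bg"],
    stimulusStates = states,
    plantedCalls = planted,
    arStimuli = setNames(arStimuli, seq_len(config$nArs)),
    arSigns = setNames(arSigns, seq_len(config$nArs)))
  list(features = features, subsystems = subsystems, network = net,
       expression = se, truth = truth, config = config)
}

#' Write a simulated compendium to disk
#'
#' Emits exactly the file formats the pipeline reads: \code{expression.tsv},
#' \code{metadata.tsv}, \code{features.gff3}, \code{subsystems.tsv},
#' \code{network.tsv}, \code{config.json} and \code{truth.json} (planted AR
#' assignments and constitutive gene sets).
#'
#' @param sim output of [simulateCompendium()]
#' @param dir output directory (created if absent)
#' @return \code{dir}, invisibly
#' @export
writeCompendium <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeExpressionMatrix(sim$expression, file.path(dir, "expression.tsv"))
  writeSampleMetadata(sim$expression, file.path(dir, "metadata.tsv"))
  writeGeneFeatures(sim$features, file.path(dir, "features.gff3"))
  writeSubsystems(sim$subsystems, file.path(dir, "subsystems.tsv"))
  writeRegulatoryNetwork(sim$network, file.path(dir, "network.tsv"))
  jsonlite::write_json(unclass(sim$config), file.path(dir, "config.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  jsonlite::write_json(
    list(arAssignments = as.list(sim$truth$arAssignments),
         alwaysOn = sim$truth$alwaysOn, alwaysOff = sim$truth$alwaysOff),
    file.path(dir, "truth.json"), auto_unbox = TRUE)
  invisible(dir)
}
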