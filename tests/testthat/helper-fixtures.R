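## Shared fixtures: encodings of the published sucrose worked example and the
## curation case-study tables, plus small builders for synthetic inputs.

fixturePath <- function(name) {
  p <- system.file("extdata", name, package = "AtomicRegulons")
  if (!nzchar(p)) stop("fixture not installed: ", name)
  p
}

sucroseNetwork <- function() readRegulatoryNetwork(fixturePath("sucrose_network.tsv"))

## genome-ish order used throughout the sucrose tests
sucroseGenes <- c("ywdA", "sacA", "sacP", "sacX", "sacY", "sacB", "levB",
                  "yveA")

## Continuous expression simulated from the sucrose stimulus structure:
## 24 samples; fructose-bisphosphate/glucose-6-phosphate active in samples
## 1-6, the sacX/sacY uncharacterized effector in 7-10, the two sacB/levB
## uncharacterized effectors in 11-14 and 15-17, yveA's extra effector in
## 18-20, sucrose itself in 21-23; sample 24 is a control.
sucroseExpression <- function(noiseSd = 0.15, seed = 101) {
  on <- list(
    ywdA = c(1:6, 21:23), sacA = c(1:6, 21:23), sacP = c(1:6, 21:23),
    sacX = c(7:10, 21:23), sacY = c(7:10, 21:23),
    sacB = c(11:17, 21:23), levB = c(11:17, 21:23),
    yveA = c(11:20, 21:23))
  set.seed(seed)
  m <- matrix(6, length(sucroseGenes), 24,
              dimnames = list(sucroseGenes, sprintf("S%02d", 1:24)))
  for (g in sucroseGenes) m[g, on[[g]]] <- 9
  m <- m + matrix(rnorm(length(m), 0, noiseSd), nrow(m))
  m
}

caseStudyNetwork <- function() readRegulatoryNetwork(fixturePath("case_study_network.tsv"))

## AR fixtures 56 / 332 / 612 / 651 with the published average PCCs; AR 651
## carries the tabulated 261 OFF / 4 ON sample counts.
caseStudyARs <- function() {
  mb <- rbind(
    data.frame(ar_id = 56L,
               locus_tag = c("zur", "hemL", "hemB", "hemD", "hemC", "hemX",
                             "hemA"),
               avg_pcc = c(0.664, 0.885, 0.900, 0.905, 0.906, 0.893, 0.804)),
    data.frame(ar_id = 332L,
               locus_tag = c("treP", "treA", "treR", "yfkO"),
               avg_pcc = c(0.807, 0.814, 0.734, 0.706)),
    data.frame(ar_id = 612L,
               locus_tag = c("yclN", "yclO", "yclP", "yclQ", "yetG", "yetH",
                             "yfmF", "yfmE", "yfmD", "yfmC", "yhfQ"),
               avg_pcc = c(0.804, 0.807, 0.815, 0.806, 0.716, 0.605, 0.621,
                           0.702, 0.769, 0.764, 0.779)),
    data.frame(ar_id = 651L,
               locus_tag = c("yosW", "yosV", "yojW"),
               avg_pcc = c(0.906, 0.948, 0.941)))
  AtomicRegulonSet(mb,
                   onCount = c(0L, 0L, 0L, 4L),
                   offCount = c(0L, 0L, 0L, 261L))
}

## small GRanges feature builder: one contig, explicit starts/strands
makeFeatures <- function(starts, ends, strands, tags = NULL,
                         contig = "chr") {
  if (is.null(tags)) tags <- sprintf("g%02d", seq_along(starts))
  GenomicRanges::GRanges(
    seqnames = contig,
    ranges = IRanges::IRanges(start = starts, end = ends),
    strand = strands, locus_tag = tags, name = tags,
    product = NA_character_)
}

## ARI of an inferred AR set against a simulation's planted assignment;
## unplaced planted genes count as singletons
truthARI <- function(ars, sim) {
  truth <- sim$truth$arAssignments
  mb <- arMembership(ars)
  inf <- setNames(rep(NA_character_, length(truth)), names(truth))
  hit <- mb$locus_tag %in% names(truth)
  inf[mb$locus_tag[hit]] <- as.character(mb$ar_id[hit])
  un <- which(is.na(inf))
  inf[un] <- paste0("unplaced_", seq_along(un))
  partitionARI(inf, truth)
}

## AtomicRegulonSet carrying the planted truth (consensus = planted profiles)
plantedARSet <- function(sim) {
  truth <- sim$truth
  k <- length(truth$ars)
  prof <- matrix(NA_integer_, k, ncol(truth$plantedCalls),
                 dimnames = list(as.character(seq_len(k)),
                                 colnames(truth$plantedCalls)))
  for (i in seq_len(k))
    prof[i, ] <- truth$plantedCalls[truth$ars[[i]][1], ]
  mb <- data.frame(ar_id = rep(seq_len(k), lengths(truth$ars)),
                   locus_tag = unlist(truth$ars, use.names = FALSE),
                   avg_pcc = NA_real_)
  AtomicRegulonSet(mb, consensus = prof)
}

## fraction of planted ARs whose top enrichment term names a true stimulus or
## its home study
enrichmentRecovery <- function(sim) {
  ars <- plantedARSet(sim)
  bsm <- binarizeExpression(sim$expression)
  cd <- SummarizedExperiment::colData(sim$expression)
  homeOf <- apply(sim$truth$stimulusStates, 1,
                  function(v) cd$study_id[which(v == 1L)[1]])
  k <- length(sim$truth$ars)
  ok <- 0L
  for (i in seq_len(k)) {
    e <- enrichMetadata(ars, bsm, i)
    top <- e$term[1]
    stims <- sim$truth$arStimuli[[as.character(i)]]
    hit <- any(vapply(stims, function(s) grepl(s, top, fixed = TRUE),
                      logical(1))) || top %in% homeOf[stims]
    if (hit) ok <- ok + 1L
  }
  ok / k
}

## brute-force signature grouping: paste sorted "stimulus|sign" strings
oracleSignatureClasses <- function(net, genes) {
  sigs <- stimulusSignatures(net, genes)
  key <- vapply(sigs, function(s)
    paste(sort(paste(s$stimulus_id, s$sign, sep = "|")), collapse = ";"),
    character(1))
  split(genes, key)
}

runInference <- function(sim, ...) {
  bsm <- binarizeExpression(sim$expression)
  drafts <- buildDraftRegulons(predictOperons(sim$features), sim$subsystems)
  inferAtomicRegulons(drafts, bsm, sim$expression, ...)
}

## small-but-complete simulation config for fast tests
smallConfig <- function(seed = 7, nGenes = 300, nArs = 8, nSamples = 40,
                        nStudies = 8, nStimuli = 16, ...) {
  syntheticConfig(nGenes = nGenes, nArs = nArs, nSamples = nSamples,
                  nStudies = nStudies, nStimuli = nStimuli, seed = seed, ...)
}
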