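test_that("a six-gene two-stimulus toy yields three theoretical ARs", {
  lnk <- data.frame(
    regulator_id = NA_character_,
    stimulus_id = c("s1", "s1", "s1", "s1", "s2", "s2", "s2", "s2"),
    target_gene = c("G1", "G2", "G3", "G4", "G3", "G4", "G5", "G6"),
    sign = "induced")
  sti <- data.frame(id = c("s1", "s2"), name = c("s1", "s2"),
                    category = "environmental", characterized = TRUE)
  net <- RegulatoryNetwork(stimuli = sti, links = lnk)
  ta <- theoreticalARs(net, paste0("G", 1:6))
  expect_length(ta$classes, 3L)
  expect_setequal(ta$classes[[1]], c("G1", "G2"))
  expect_setequal(ta$classes[[2]], c("G3", "G4"))
  expect_setequal(ta$classes[[3]], c("G5", "G6"))
  ## all genes sharing one stimulus collapse to a single class
  net1 <- RegulatoryNetwork(stimuli = sti[1, ],
                            links = lnk[lnk$stimulus_id == "s1", ])
  expect_length(theoreticalARs(net1, paste0("G", 1:4))$classes, 1L)
})

test_that("the sucrose map yields classes 3/2/2 with yveA unplaced", {
  net <- sucroseNetwork()
  ta <- theoreticalARs(net, sucroseGenes)
  expect_length(ta$classes, 3L)
  expect_equal(sort(lengths(ta$classes), decreasing = TRUE),
               c(3L, 2L, 2L), ignore_attr = TRUE)
  expect_equal(ta$unplaced, "yveA")
  expect_equal(ta$n_signatures, 4L)
})

test_that("theoretical ARs match the brute-force signature oracle", {
  sim <- simulateCompendium(syntheticConfig(nGenes = 1000, nArs = 30,
                                            nSamples = 40, nStudies = 8,
                                            nStimuli = 40, seed = 31))
  universe <- names(sim$truth$arAssignments)
  ta <- theoreticalARs(sim$network, universe)
  oracle <- oracleSignatureClasses(sim$network, universe)
  oracle <- oracle[lengths(oracle) >= 2]
  expect_length(ta$classes, length(oracle))
  expect_setequal(lapply(ta$classes, sort), lapply(unname(oracle), sort))
  ## and they equal the planted ARs exactly
  planted <- lapply(sim$truth$ars, sort)
  expect_setequal(lapply(ta$classes, sort), unname(planted))
})

test_that("the four consistency categories match the case-study tables", {
  net <- caseStudyNetwork()
  ars <- caseStudyARs()
  cl <- classifyConsistency(ars, net)
  expect_equal(unname(cl["332"]), "inconsistent")
  expect_equal(unname(cl["612"]), "consistent_missing")
  expect_equal(unname(cl["651"]), "empty")
  ## zur prints no stimuli, so pre-curation AR 56 is consistent_missing
  expect_equal(unname(cl["56"]), "consistent_missing")
  rep <- consistencyReport(ars, net)
  expect_equal(sum(rep@summary$count), 4L)
  expect_true(all(table(rep@perAR$category)[rep@summary$category[
    rep@summary$count > 0]] == rep@summary$count[rep@summary$count > 0]))
})

test_that("consistency categories are exhaustive and exclusive", {
  sim <- simulateCompendium(smallConfig(seed = 32))
  ars <- runInference(sim)
  rep <- consistencyReport(ars, sim$network)
  expect_equal(nrow(rep@perAR), length(arIds(ars)))
  expect_equal(sum(rep@summary$count), length(arIds(ars)))
  expect_false(anyDuplicated(rep@perAR$ar_id) > 0)
  expect_true(all(rep@perAR$category %in%
    c("consistent", "consistent_missing", "inconsistent", "empty")))
})

test_that("sign agreement is required only when both signs are known", {
  mkNet <- function(signA, signB) {
    lnk <- data.frame(regulator_id = NA_character_,
                      stimulus_id = "s1",
                      target_gene = c("gA", "gB"),
                      sign = c(signA, signB))
    RegulatoryNetwork(stimuli = data.frame(id = "s1", name = "s1",
                                           category = "biochemical",
                                           characterized = TRUE),
                      links = lnk)
  }
  mkAR <- function() AtomicRegulonSet(data.frame(
    ar_id = 1L, locus_tag = c("gA", "gB"), avg_pcc = NA_real_))
  expect_equal(unname(classifyConsistency(mkAR(), mkNet("induced", "induced"))),
               "consistent")
  expect_equal(unname(classifyConsistency(mkAR(), mkNet("induced", "unknown"))),
               "consistent")
  expect_equal(unname(classifyConsistency(mkAR(), mkNet("induced", "repressed"))),
               "inconsistent")
})

test_that("stripping regulators makes AR 56 consistent, then curation fixes AR 332", {
  net <- caseStudyNetwork()
  ars <- caseStudyARs()
  st <- stripRegulators(ars, net)
  expect_true("zur" %in% st$log$gene)
  expect_true("treR" %in% st$log$gene)
  expect_false(any(c("zur", "treR") %in% arMembership(st$ars)$locus_tag))
  expect_length(arGenes(st$ars)[["56"]], 6L)
  cl <- classifyConsistency(st$ars, net)
  expect_equal(unname(cl["56"]), "consistent")
  expect_equal(unname(cl["332"]), "inconsistent")  # yfkO still discordant
  cu <- dropDiscordantMembers(st$ars, net)
  expect_equal(cu$log$gene, "yfkO")
  cl2 <- classifyConsistency(cu$ars, net)
  expect_equal(unname(cl2["332"]), "consistent")
  ## never a worse category after curation
  rank <- c(consistent = 1, consistent_missing = 2, empty = 3,
            inconsistent = 4)
  expect_true(all(rank[cl2[names(cl)]] <= rank[cl]))
  ## an AR without regulator members is untouched
  expect_setequal(arGenes(st$ars)[["651"]], arGenes(ars)[["651"]])
})

test_that("stripping flags ARs that fall under the size minimum", {
  lnk <- data.frame(regulator_id = "RegX", stimulus_id = "s1",
                    target_gene = c("r1", "t1"), sign = "induced")
  net <- RegulatoryNetwork(
    regulators = data.frame(id = "RegX", name = "RegX",
                            encoding_gene = "r1", mechanism = "TF"),
    stimuli = data.frame(id = "s1", name = "s1", category = "biochemical",
                         characterized = TRUE),
    links = lnk)
  ars <- AtomicRegulonSet(data.frame(ar_id = 1L,
                                     locus_tag = c("r1", "t1"),
                                     avg_pcc = NA_real_))
  st <- stripRegulators(ars, net)
  expect_equal(st$flagged, 1L)
  expect_equal(arMembership(st$ars)$locus_tag, "t1")  # not deleted
})

test_that("stimulus propagation proposes links for unannotated members", {
  net <- caseStudyNetwork()
  ars <- caseStudyARs()
  pr <- propagateStimuli(ars, net, 612)
  expect_equal(nrow(pr), 2L)
  expect_setequal(pr$target_gene, c("yetG", "yetH"))
  expect_equal(unique(pr$stimulus_id), "iron")
  expect_equal(unique(pr$regulator_id), "Fur")
  ## applies only to consistent_missing ARs
  expect_error(propagateStimuli(ars, net, 651), "empty")
  st <- stripRegulators(ars, net)
  expect_error(propagateStimuli(st$ars, net, 56), "consistent")
})

test_that("propagation over k empty members and m stimuli yields k*m links", {
  lnk <- rbind(
    expand.grid(regulator_id = "R1", stimulus_id = c("s1", "s2", "s3"),
                target_gene = c("a", "b", "c"), stringsAsFactors = FALSE))
  lnk$sign <- "induced"
  net <- RegulatoryNetwork(
    regulators = data.frame(id = "R1", name = "R1",
                            encoding_gene = NA_character_, mechanism = "TF"),
    stimuli = data.frame(id = c("s1", "s2", "s3"), name = c("s1", "s2", "s3"),
                         category = "biochemical", characterized = TRUE),
    links = lnk,
    genes = c("a", "b", "c", "x", "y"))
  ars <- AtomicRegulonSet(data.frame(ar_id = 1L,
                                     locus_tag = c("a", "b", "c", "x", "y"),
                                     avg_pcc = NA_real_))
  pr <- propagateStimuli(ars, net, 1)
  expect_equal(nrow(pr), 6L)  # cross product: 2 empty members x 3 stimuli
  expect_equal(as.vector(table(pr$target_gene)), c(3L, 3L))
  expect_equal(unique(pr$regulator_id), "R1")
})

test_that("the 3-of-3 term overlap in 10 samples scores exactly 1/120", {
  cons <- matrix(c(rep(1L, 3), rep(0L, 7)), 1,
                 dimnames = list("1", sprintf("s%02d", 1:10)))
  ars <- AtomicRegulonSet(data.frame(ar_id = 1L,
                                     locus_tag = c("gA", "gB"),
                                     avg_pcc = NA_real_),
                          consensus = cons)
  cd <- S4Vectors::DataFrame(
    study_id = rep(NA_character_, 10),
    description = c(rep("sporulation induced", 3), rep("exponential", 7)),
    row.names = colnames(cons))
  bsm <- BinaryStateMatrix(
    matrix(0L, 1, 10, dimnames = list("gA", colnames(cons))), colData = cd)
  e <- enrichMetadata(ars, bsm, 1)
  sp <- e[e$term == "sporulation", ]
  expect_equal(sp$p, 1 / choose(10, 3), tolerance = 1e-12)
  expect_equal(sp$overlap, 3L)
  ## a term present in every sample is uninformative: p = 1
  cd2 <- cd
  cd2$description <- paste(cd2$description, "biofilm")
  bsm2 <- BinaryStateMatrix(
    matrix(0L, 1, 10, dimnames = list("gA", colnames(cons))), colData = cd2)
  e2 <- enrichMetadata(ars, bsm2, 1)
  expect_equal(e2$p[e2$term == "biofilm"], 1)
})

test_that("a study whose samples are exactly the ON set ranks first", {
  nS <- 20
  cons <- matrix(c(rep(1L, 3), rep(0L, nS - 3)), 1,
                 dimnames = list("1", sprintf("s%02d", 1:nS)))
  ars <- AtomicRegulonSet(data.frame(ar_id = 1L,
                                     locus_tag = c("gA", "gB"),
                                     avg_pcc = NA_real_),
                          consensus = cons)
  cd <- S4Vectors::DataFrame(
    study_id = c(rep("study0003", 3), rep(sprintf("study%04d", 4:20), 1)),
    description = c(rep(
      "Tested gene expression at regular intervals after sporulation was induced",
      3), sprintf("unrelated growth condition number %d", 4:20)),
    row.names = colnames(cons))
  bsm <- BinaryStateMatrix(
    matrix(0L, 1, nS, dimnames = list("gA", colnames(cons))), colData = cd)
  e <- enrichMetadata(ars, bsm, 1)
  expect_equal(e$term[1], "study0003")
  expect_true(e$candidate[1])
  ## never-ON ARs cannot be enriched
  consOff <- matrix(rep(0L, nS), 1,
                    dimnames = list("1", colnames(cons)))
  arsOff <- AtomicRegulonSet(data.frame(ar_id = 1L, locus_tag = c("gA", "gB"),
                                        avg_pcc = NA_real_),
                             consensus = consOff)
  expect_error(enrichMetadata(arsOff, bsm, 1), "never ON")
})

test_that("essential genes never sit among the always-OFF set", {
  expect_equal(essentialCheck(c("a", "b"), c("c", "d")), character(0))
  expect_equal(essentialCheck(c("a", "b", "e2"), c("e1", "e2")), "e2")
  set.seed(33)
  off <- sample(letters, 10)
  ess <- sample(letters, 8)
  expect_equal(essentialCheck(off, ess),
               sort(letters[letters %in% off & letters %in% ess]))
})
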