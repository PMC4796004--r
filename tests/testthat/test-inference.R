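test_that("profile identity tolerates UNCERTAIN and counts co-decided", {
  a <- c(1L, 0L, 1L, NA, rep(1L, 8))
  expect_true(profilesIdentical(a, a))
  b <- a; b[4] <- 0L
  expect_true(profilesIdentical(a, b))      # NA never conflicts
  b2 <- a; b2[1] <- 0L
  expect_false(profilesIdentical(a, b2))    # one decided disagreement
  expect_false(profilesIdentical(a[1:6], a[1:6]))  # < minCodecided
  expect_true(profilesIdentical(a[1:6], a[1:6], minCodecided = 5))
  expect_error(profilesIdentical(a, a[-1]), "lengths")
})

test_that("one conflict among 200 samples is caught, matching an elementwise scan", {
  set.seed(13)
  a <- sample(c(0L, 1L), 200, replace = TRUE)
  b <- a
  i <- sample(200, 1)
  b[i] <- 1L - b[i]
  oracle <- any(!is.na(a) & !is.na(b) & a != b)
  expect_true(oracle)
  expect_false(profilesIdentical(a, b))
  expect_true(profilesIdentical(a, a))
})

test_that("three planted co-expressed genes in one draft become a single AR", {
  prof <- c(rep(0L, 10), rep(1L, 10))
  m <- 6 + 3 * rbind(g1 = prof, g2 = prof, g3 = prof)
  colnames(m) <- sprintf("s%02d", 1:20)
  bsm <- binarizeExpression(m)
  ars <- inferAtomicRegulons(list(c("g1", "g2", "g3")), bsm, m)
  expect_equal(length(arIds(ars)), 1L)
  expect_setequal(arGenes(ars)[["1"]], c("g1", "g2", "g3"))
  expect_equal(unname(onCount(ars)), 10L)
  expect_equal(unname(offCount(ars)), 10L)
  expect_true(all(arMembership(ars)$avg_pcc > 0.99))
})

test_that("the sucrose stimulon decomposes into three ARs with yveA unplaced", {
  m <- sucroseExpression()
  bsm <- binarizeExpression(m)
  ars <- inferAtomicRegulons(list(sucroseGenes), bsm, m)
  g <- arGenes(ars)
  expect_length(g, 3L)
  expect_setequal(g[["1"]], c("ywdA", "sacA", "sacP"))
  expect_setequal(g[["2"]], c("sacX", "sacY"))
  expect_setequal(g[["3"]], c("sacB", "levB"))
  expect_equal(unplaced(ars), "yveA")
})

test_that("inference is idempotent on an AR's own genes", {
  m <- sucroseExpression()
  bsm <- binarizeExpression(m)
  ars <- inferAtomicRegulons(list(sucroseGenes), bsm, m)
  for (id in names(arGenes(ars))) {
    g <- arGenes(ars)[[id]]
    again <- inferAtomicRegulons(list(g), bsm, m)
    expect_length(arGenes(again), 1L)
    expect_setequal(arGenes(again)[["1"]], g)
    expect_equal(unname(onCount(again)),
                 unname(onCount(ars)[id]))
  }
})

test_that("missing genes in calls or expression raise errors", {
  m <- sucroseExpression()
  bsm <- binarizeExpression(m)
  expect_error(inferAtomicRegulons(list(c("ywdA", "ghost")), bsm, m),
               "absent from the call matrix: ghost")
  expect_error(inferAtomicRegulons(list(c("ywdA", "sacA")), bsm,
                                   m[setdiff(rownames(m), "sacA"), ]),
               "absent from expression: sacA")
  expect_error(
    inferAtomicRegulons(list(c("ywdA"), c("ywdA", "sacA")), bsm, m),
    "more than one draft")
})

test_that("AR output is a min-size partition with conflict-free members", {
  sim <- simulateCompendium(smallConfig(seed = 21))
  bsm <- binarizeExpression(sim$expression)
  ars <- runInference(sim)
  mb <- arMembership(ars)
  ## partition: no gene twice, none also unplaced
  expect_false(anyDuplicated(mb$locus_tag) > 0)
  expect_length(intersect(mb$locus_tag, unplaced(ars)), 0L)
  expect_true(all(table(mb$ar_id) >= 2L))
  ## zero within-AR conflicts and identical decided states per sample
  cm <- calls(bsm)
  for (id in names(arGenes(ars))) {
    sub <- cm[arGenes(ars)[[id]], , drop = FALSE]
    nOn <- colSums(sub == 1L, na.rm = TRUE)
    nOff <- colSums(sub == 0L, na.rm = TRUE)
    expect_false(any(nOn > 0 & nOff > 0))
  }
  ## members share ON/OFF counts over co-decided samples (pairwise)
  for (id in head(names(arGenes(ars)), 10)) {
    sub <- cm[arGenes(ars)[[id]], , drop = FALSE]
    dec <- colSums(is.na(sub)) == 0
    if (sum(dec) == 0) next
    onPer <- rowSums(sub[, dec, drop = FALSE] == 1L)
    expect_equal(unname(onPer), rep(unname(onPer[1]), nrow(sub)))
  }
})

test_that("noiseless inference equals brute-force call-vector classes", {
  sim <- simulateCompendium(smallConfig(seed = 22, nGenes = 100, nArs = 5,
                                        noiseSd = 0))
  bsm <- binarizeExpression(sim$expression, uncertainBand = 0)
  cm <- calls(bsm)
  ars <- runInference(sim)
  ## brute force: exact call-string classes among genes with non-constant
  ## expression (constant genes cannot pass the correlation merge gate
  ## across drafts, so they group within their own draft)
  key <- apply(cm, 1, paste, collapse = "")
  varying <- rownames(cm)[apply(cm, 1, function(v) length(unique(v)) > 1)]
  classes <- split(varying, key[varying])
  classes <- classes[lengths(classes) >= 2]
  inferred <- arGenes(ars)
  for (cl in classes) {
    hit <- vapply(inferred, function(g) setequal(g, cl), logical(1))
    expect_equal(sum(hit), 1L)
  }
})

test_that("always-ON, always-OFF and differential ARs are told apart", {
  cons <- rbind(`1` = rep(1L, 8),
                `2` = rep(0L, 8),
                `3` = c(rep(0L, 6), 1L, 1L),
                `4` = c(rep(1L, 7), NA))
  mb <- data.frame(ar_id = rep(1:4, each = 2),
                   locus_tag = paste0("g", 1:8), avg_pcc = NA_real_)
  ars <- AtomicRegulonSet(mb, consensus = cons)
  cats <- categorizeARs(ars)
  expect_equal(cats$always_on, c("1", "4"))
  expect_equal(cats$always_off, "2")
  expect_equal(cats$differential, "3")
  expect_equal(unname(cats$gene_counts),
               c(4L, 2L, 2L))
  ## brute-force tally agreement on a random AR set
  set.seed(23)
  cons2 <- matrix(sample(c(0L, 1L, NA), 60, TRUE), 6, 10,
                  dimnames = list(as.character(1:6), NULL))
  mb2 <- data.frame(ar_id = rep(1:6, each = 2),
                    locus_tag = paste0("h", 1:12), avg_pcc = NA_real_)
  ars2 <- AtomicRegulonSet(mb2, consensus = cons2)
  cats2 <- categorizeARs(ars2)
  for (i in 1:6) {
    on <- sum(cons2[i, ] == 1L, na.rm = TRUE)
    off <- sum(cons2[i, ] == 0L, na.rm = TRUE)
    want <- if (off == 0 && on > 0) "always_on"
      else if (on == 0 && off > 0) "always_off" else "differential"
    expect_true(as.character(i) %in% cats2[[want]])
  }
})

test_that("AR tables round-trip through TSV", {
  m <- sucroseExpression()
  bsm <- binarizeExpression(m)
  ars <- inferAtomicRegulons(list(sucroseGenes), bsm, m)
  f <- withr::local_tempfile(fileext = ".tsv")
  writeAtomicRegulons(ars, f)
  back <- readAtomicRegulons(f)
  expect_equal(arGenes(back), arGenes(ars))
  expect_equal(unname(onCount(back)), unname(onCount(ars)))
  expect_equal(arMembership(back)$avg_pcc, arMembership(ars)$avg_pcc,
               tolerance = 1e-3)
})
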