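## Independent oracle: exhaustive scan of every cut of the sorted values,
## scoring total within-cluster sum of squares directly.
oracleSplit <- function(x) {
  s <- sort(x)
  n <- length(s)
  best <- NULL
  for (k in seq_len(n - 1)) {
    lo <- s[1:k]; hi <- s[(k + 1):n]
    ss <- sum((lo - mean(lo))^2) + sum((hi - mean(hi))^2)
    if (is.null(best) || ss < best$ss)
      best <- list(ss = ss, mid = (s[k] + s[k + 1]) / 2,
                   gap = mean(hi) - mean(lo))
  }
  best
}

test_that("a clean two-level gene is called by the exhaustive-split oracle", {
  x <- c(1, 1, 1, 10, 10)
  b <- oracleSplit(x)
  expect_equal(b$mid, 5.5)
  cm <- calls(binarizeExpression(matrix(x, 1), minSeparation = 1.0))[1, ]
  expect_equal(unname(cm), ifelse(x >= b$mid, 1L, 0L))
  expect_equal(unname(cm), c(0L, 0L, 0L, 1L, 1L))
})

test_that("binarize matches the oracle midpoint on random bimodal genes", {
  set.seed(3)
  for (r in 1:20) {
    n <- sample(6:40, 1)
    x <- c(rnorm(n, 2, 0.2), rnorm(sample(2:10, 1), 8, 0.2))
    b <- oracleSplit(x)
    cm <- calls(binarizeExpression(matrix(x, 1), uncertainBand = 0))[1, ]
    expect_equal(unname(cm), ifelse(x >= b$mid, 1L, 0L))
  }
})

test_that("constant genes are unimodal: ON at the global maximum, OFF low", {
  m <- rbind(hi = rep(10, 6), lo = rep(1, 6),
             mid = c(4, 4, 4, 10, 10, 10))
  cm <- calls(binarizeExpression(m))
  expect_equal(unname(cm["hi", ]), rep(1L, 6))
  expect_equal(unname(cm["lo", ]), rep(0L, 6))
})

test_that("single-sample matrices are rejected", {
  expect_error(binarizeExpression(matrix(1:5, ncol = 1)), "2 samples")
})

test_that("duplicated sample columns get identical calls", {
  set.seed(4)
  m <- matrix(rnorm(60, 6, 0.3), 3, 20)
  m[2, 1:8] <- m[2, 1:8] + 3
  m2 <- cbind(m, m)
  colnames(m2) <- sprintf("S%02d", 1:40)
  cm <- calls(binarizeExpression(m2))
  expect_identical(cm[, 1:20], cm[, 21:40, drop = FALSE],
                   ignore_attr = TRUE)
  expect_equal(unname(cm[, 1:20]), unname(cm[, 21:40]))
})

test_that("binarization is invariant under sample reordering", {
  set.seed(5)
  m <- matrix(rnorm(200, 6, 0.4), 5, 40,
              dimnames = list(paste0("g", 1:5), sprintf("S%02d", 1:40)))
  m[1, 1:10] <- m[1, 1:10] + 3
  m[3, 30:40] <- m[3, 30:40] + 3
  perm <- sample(40)
  cm1 <- calls(binarizeExpression(m))
  cm2 <- calls(binarizeExpression(m[, perm]))
  expect_identical(cm2, cm1[, perm])
})

test_that("raising one value of a bimodal gene never flips a call ON to OFF", {
  set.seed(6)
  for (r in 1:50) {
    x <- c(rnorm(15, 6, 0.3), rnorm(sample(3:12, 1), 9, 0.3))
    before <- calls(binarizeExpression(matrix(x, 1)))[1, ]
    i <- sample(length(x), 1)
    y <- x
    y[i] <- y[i] + runif(1, 0, 3)
    after <- calls(binarizeExpression(matrix(y, 1)))[1, ]
    flipped <- !is.na(before) & !is.na(after) & before == 1L & after == 0L
    expect_false(any(flipped))
  }
})

test_that("call error stays below 1% at noise 0.2 x minimum separation", {
  set.seed(8)
  nG <- 100; nS <- 100  # 10^4 cells
  planted <- matrix(rbinom(nG * nS, 1, 0.4), nG, nS)
  m <- 6 + 3 * planted + matrix(rnorm(nG * nS, 0, 0.2), nG, nS)
  cm <- calls(binarizeExpression(m, minSeparation = 1.0))
  wrong <- sum(!is.na(cm) & cm != planted)
  expect_lt(wrong / (nG * nS), 0.01)
})

test_that("state counts sum to the sample count and match a direct tally", {
  set.seed(9)
  m <- matrix(sample(c(0L, 1L, NA), 120, replace = TRUE), 6, 20,
              dimnames = list(paste0("g", 1:6), paste0("s", 1:20)))
  sc <- stateCounts(BinaryStateMatrix(m))
  expect_true(all(sc$on + sc$off + sc$uncertain == 20L))
  for (i in 1:6) {
    expect_equal(sc$on[i], sum(m[i, ] == 1L, na.rm = TRUE))
    expect_equal(sc$off[i], sum(m[i, ] == 0L, na.rm = TRUE))
    expect_equal(sc$uncertain[i], sum(is.na(m[i, ])))
  }
})

test_that("an AR tabulated as 261 OFF / 4 ON tallies exactly", {
  prof <- c(rep(0L, 261), rep(1L, 4))
  m <- rbind(yosW = prof, yosV = prof, yojW = prof)
  colnames(m) <- sprintf("s%03d", seq_len(ncol(m)))
  sc <- stateCounts(BinaryStateMatrix(m))
  expect_equal(sc$off, rep(261L, 3))
  expect_equal(sc$on, rep(4L, 3))
  ## differential per the always-ON/OFF definition
  ars <- caseStudyARs()
  cats <- categorizeARs(ars)
  expect_true("651" %in% cats$differential)
})

test_that("changed-state queries are symmetric and skip UNCERTAIN calls", {
  m <- rbind(a = c(0L, 1L), b = c(1L, 1L), c = c(NA, 1L), d = c(1L, 0L))
  colnames(m) <- c("ctrl", "mmc")
  x <- BinaryStateMatrix(m)
  expect_equal(changedState(x, "ctrl", "mmc"), c("a", "d"))
  expect_equal(changedState(x, "mmc", "ctrl"), c("a", "d"))
  expect_equal(changedState(x, "ctrl", "ctrl"), character(0))
  expect_error(changedState(x, "ctrl", "nope"), "unknown sample id: nope")
})

test_that("prophage-like induction is recovered between control and treated", {
  ## genes OFF everywhere except a treated sample; like mitomycin C induction
  set.seed(10)
  nS <- 30
  m <- matrix(rnorm(20 * nS, 6, 0.2), 20, nS,
              dimnames = list(sprintf("pg%02d", 1:20), sprintf("s%02d", 1:nS)))
  prophage <- sprintf("pg%02d", 1:5)
  m[prophage, c(28, 29, 30)] <- m[prophage, c(28, 29, 30)] + 3
  bsm <- binarizeExpression(m)
  expect_setequal(changedState(bsm, "s01", "s30"), prophage)
})

test_that("expression round-trips through TSV with metadata", {
  sim <- simulateCompendium(smallConfig())
  d <- withr::local_tempdir()
  writeExpressionMatrix(sim$expression, file.path(d, "e.tsv"))
  writeSampleMetadata(sim$expression, file.path(d, "m.tsv"))
  se <- readExpressionMatrix(file.path(d, "e.tsv"),
                             metadataPath = file.path(d, "m.tsv"))
  expect_equal(SummarizedExperiment::assay(se, "exprs"),
               SummarizedExperiment::assay(sim$expression, "exprs"),
               tolerance = 1e-8)
  expect_equal(se$study_id, sim$expression$study_id)
})

test_that("GEO series-matrix shaped files import", {
  f <- withr::local_tempfile(fileext = ".txt")
  gsm <- sprintf("GSM%03d", 1:4)
  lines <- c(
    "!Series_title\t\"tiny compendium\"",
    paste0("!Sample_geo_accession\t",
           paste(sprintf('"%s"', gsm), collapse = "\t")),
    paste0("!Sample_title\t",
           paste(sprintf('"condition %d"', 1:4), collapse = "\t")),
    "!series_matrix_table_begin",
    paste(c("ID_REF", gsm), collapse = "\t"),
    paste(c("geneA", 6.1, 6.0, 9.2, 9.1), collapse = "\t"),
    paste(c("geneB", 8.9, 9.0, 6.2, 6.1), collapse = "\t"),
    "!series_matrix_table_end")
  writeLines(lines, f)
  se <- readGEOSeriesMatrix(f)
  expect_equal(dim(se), c(2L, 4L))
  expect_equal(colnames(se), gsm)
  expect_equal(se$description, sprintf("condition %d", 1:4))
  cm <- calls(binarizeExpression(se))
  expect_equal(unname(cm["geneA", ]), c(0L, 0L, 1L, 1L))
})
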