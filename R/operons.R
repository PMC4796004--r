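## Crude operon prediction and subsystem-seeded draft regulons.

#' Read gene features
#'
#' Reads gene features as a [GenomicRanges::GRanges] with metadata columns
#' \code{locus_tag}, \code{name} and \code{product}. GFF3 input is parsed with
#' \pkg{rtracklayer} (CDS/gene rows carrying a \code{locus_tag} attribute);
#' the TSV fallback expects columns \code{locus_tag}, \code{name},
#' \code{contig}, \code{start}, \code{end}, \code{strand}, \code{function}.
#' Coordinates are 1-based inclusive.
#'
#' @param path GFF3 or TSV file
#' @param format \code{"auto"} (by extension), \code{"gff3"} or \code{"tsv"}
#' @return GRanges sorted by (contig, start)
#' @export
readGeneFeatures <- function(path, format = c("auto", "gff3", "tsv")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("features file not found: ", path)
  if (format == "auto")
    format <- if (grepl("\\.gff3?$", path, ignore.case = TRUE)) "gff3" else "tsv"
  if (format == "gff3") {
    gr <- rtracklayer::import(path, format = "gff3")
    gr <- gr[!is.na(gr$locus_tag)]
    if ("type" %in% names(S4Vectors::mcols(gr)) &&
        any(gr$type %in% c("CDS", "gene")))
      gr <- gr[gr$type %in% c("CDS", "gene")]
    gr <- gr[!duplicated(gr$locus_tag)]
    mc <- S4Vectors::mcols(gr)
    S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
      locus_tag = as.character(gr$locus_tag),
      name = if ("Name" %in% names(mc)) as.character(mc$Name)
             else as.character(gr$locus_tag),
      product = if ("product" %in% names(mc)) as.character(mc$product)
                else NA_character_)
  } else {
    tab <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
    need <- c("locus_tag", "contig", "start", "end", "strand")
    if (!all(need %in% names(tab)))
      stop("feature TSV must have columns: ", paste(need, collapse = ", "))
    gr <- GenomicRanges::GRanges(
      seqnames = tab$contig,
      ranges = IRanges::IRanges(start = tab$start, end = tab$end),
      strand = tab$strand,
      locus_tag = tab$locus_tag,
      name = if ("name" %in% names(tab)) tab$name else tab$locus_tag,
      product = if ("function" %in% names(tab)) tab[["function"]]
                else NA_character_)
  }
  if (anyDuplicated(gr$locus_tag)) stop("duplicate locus tags in features")
  GenomicRanges::sort(gr, ignore.strand = TRUE)
}

#' Write gene features as GFF3
#'
#' @param gr GRanges with a \code{locus_tag} column
#' @param path output path
#' @return \code{path}, invisibly
#' @export
writeGeneFeatures <- function(gr, path) {
  gr2 <- gr
  gr2$type <- "CDS"
  gr2$source <- "AtomicRegulons"
  gr2$ID <- gr2$locus_tag
  gr2$phase <- 0L
  rtracklayer::export(gr2, path, format = "gff3")
  invisible(path)
}

#' Read subsystem membership
#'
#' @param path two-column TSV: \code{subsystem}, \code{locus_tag}
#' @return named list: subsystem id -> character vector of locus tags
#' @export
readSubsystems <- function(path) {
  if (!file.exists(path)) stop("subsystems file not found: ", path)
  tab <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (ncol(tab) < 2L) stop("subsystem TSV needs columns subsystem, locus_tag")
  sp <- split(as.character(tab[[2]]), as.character(tab[[1]]))
  lapply(sp, unique)
}

#' Write subsystem membership
#'
#' @param subsystems named list of locus-tag vectors
#' @param path output path
#' @return \code{path}, invisibly
#' @export
writeSubsystems <- function(subsystems, path) {
  out <- data.frame(
    subsystem = rep(names(subsystems), lengths(subsystems)),
    locus_tag = unlist(subsystems, use.names = FALSE),
    stringsAsFactors = FALSE)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Crude operon prediction
#'
#' Partitions the genes of each contig into maximal runs of adjacent
#' same-strand genes whose intergenic gap (next start - previous end - 1,
#' negative for overlapping genes) does not exceed \code{maxGap}. Every gene
#' lands in exactly one operon; no promoter or terminator evidence is used
#' ("crude" by design). Chromosome circularity is ignored: the first and last
#' operon of a contig are never joined.
#'
#' @param features GRanges from [readGeneFeatures()] (any order; sorted
#'   internally by contig and start)
#' @param maxGap largest intergenic distance (bp) bridged within an operon
#' @return list of character vectors of locus tags, each in genome order,
#'   named \code{operon_0001}, ...; the strand of each operon is attached as
#'   attribute \code{strand}
#' @export
predictOperons <- function(features, maxGap = 150L) {
  if (anyDuplicated(features$locus_tag))
    stop("duplicate locus tags in features")
  gr <- GenomicRanges::sort(features, ignore.strand = TRUE)
  contig <- as.character(GenomicRanges::seqnames(gr))
  strand <- as.character(GenomicRanges::strand(gr))
  st <- GenomicRanges::start(gr)
  en <- GenomicRanges::end(gr)
  n <- length(gr)
  newRun <- c(TRUE, contig[-1] != contig[-n] |
                    strand[-1] != strand[-n] |
                    (st[-1] - en[-n] - 1L) > maxGap)
  runId <- cumsum(newRun)
  ops <- split(as.character(gr$locus_tag), runId)
  strands <- vapply(split(strand, runId), `[`, character(1), 1L)
  names(ops) <- sprintf("operon_%04d", seq_along(ops))
  for (i in seq_along(ops)) attr(ops[[i]], "strand") <- strands[[i]]
  ops
}

#' Build draft regulons from operons and subsystems
#'
#' Draft regulons seed AR inference: two operons are joined whenever each
#' contributes at least one gene to a common subsystem, and each connected
#' component of this operon-subsystem graph becomes one draft regulon. Operons
#' touching no subsystem remain singleton drafts.
#'
#' @param operons list of locus-tag vectors, as [predictOperons()]
#' @param subsystems named list of locus-tag vectors
#' @return list of drafts; each draft is a list with elements \code{genes}
#'   (locus tags, in the order the operons carry them), \code{operons}
#'   (operon names) and \code{subsystems} (subsystem ids shared inside the
#'   draft)
#' @export
buildDraftRegulons <- function(operons, subsystems = list()) {
  nOp <- length(operons)
  if (!nOp) return(list())
  parent <- seq_len(nOp)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  unite <- function(i, j) {
    ri <- find(i); rj <- find(j)
    if (ri != rj) parent[max(ri, rj)] <<- min(ri, rj)
  }
  geneToOp <- rep(seq_len(nOp), lengths(operons))
  names(geneToOp) <- unlist(operons, use.names = FALSE)
  subsOfOp <- vector("list", nOp)
  for (s in names(subsystems)) {
    hit <- unique(geneToOp[intersect(subsystems[[s]], names(geneToOp))])
    if (length(hit) >= 1L)
      for (i in hit) subsOfOp[[i]] <- c(subsOfOp[[i]], s)
    if (length(hit) >= 2L)
      for (i in hit[-1]) unite(hit[1], i)
  }
  comp <- vapply(seq_len(nOp), find, integer(1))
  groups <- split(seq_len(nOp), comp)
  drafts <- lapply(groups, function(idx) {
    list(genes = unlist(operons[idx], use.names = FALSE),
         operons = names(operons)[idx],
         subsystems = sort(unique(unlist(subsOfOp[idx]))))
  })
  names(drafts) <- sprintf("draft_%04d", seq_along(drafts))
  drafts
}
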