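#' Read gene models from a GFF3 file
#'
#' Parses a GFF3 file with a gene/mRNA/CDS hierarchy (ID/Parent attributes)
#' into [GeneModel-class] objects. When a gene carries several transcripts
#' the one with the longest CDS is selected, ties broken lexicographically
#' by transcript ID. GFF3 1-based inclusive coordinates are converted to the
#' internal 0-based half-open convention; minus-strand CDS segments are
#' re-ordered into transcription order.
#'
#' @param path path to a GFF3 file.
#' @param species species label to stamp on the models (GFF3 carries none).
#' @return named list of [GeneModel-class], one per gene.
#' @examples
#' dir <- tempfile(); fx <- writeFixture(dir)
#' models <- readGeneModels(fx$gff3)
#' length(models)
#' @importFrom rtracklayer import
#' @importFrom GenomicRanges start end strand seqnames mcols
#' @export
readGeneModels <- function(path, species = "unknown") {
  gr <- rtracklayer::import(path, format = "gff3")
  md <- S4Vectors::mcols(gr)
  type <- as.character(md$type)

  first_parent <- function(p) vapply(p, function(v)
    if (length(v)) v[[1L]] else NA_character_, character(1L))

  mrna <- gr[type == "mRNA"]
  cds <- gr[type == "CDS"]
  if (length(mrna) == 0L && length(cds) == 0L)
    return(stats::setNames(list(), character()))
  if (length(mrna) == 0L || length(cds) == 0L)
    stop("GFF3 file '", path, "' contains an incomplete mRNA/CDS hierarchy")
  mrna_id <- as.character(S4Vectors::mcols(mrna)$ID)
  mrna_parent <- first_parent(S4Vectors::mcols(mrna)$Parent)
  cds_parent <- first_parent(S4Vectors::mcols(cds)$Parent)
  if (anyNA(mrna_parent))
    stop("malformed GFF3 hierarchy: mRNA feature(s) without Parent: ",
         paste(mrna_id[is.na(mrna_parent)], collapse = ", "))
  orphans <- setdiff(unique(cds_parent), mrna_id)
  if (length(orphans) || anyNA(cds_parent))
    stop("malformed GFF3 hierarchy: CDS features with unknown Parent: ",
         paste(stats::na.omit(orphans), collapse = ", "))

  # pick the transcript with the longest CDS per gene (ties: lexicographic)
  cds_len <- tapply(GenomicRanges::width(cds), cds_parent, sum)
  pick <- vapply(split(mrna_id, mrna_parent), function(tx) {
    tx <- sort(tx)
    tx[which.max(cds_len[tx])]
  }, character(1L))

  bad <- character()
  models <- lapply(names(pick), function(gid) {
    tx <- pick[[gid]]
    seg <- cds[cds_parent == tx]
    seg <- seg[order(GenomicRanges::start(seg))]
    strand <- as.character(GenomicRanges::strand(seg))[1L]
    m <- cbind(start = GenomicRanges::start(seg) - 1L,
               end = GenomicRanges::end(seg))
    if (strand == "-") m <- m[rev(seq_len(nrow(m))), , drop = FALSE]
    if (sum(m[, 2L] - m[, 1L]) %% 3L != 0L) {
      bad <<- c(bad, gid)
      return(NULL)
    }
    pid <- S4Vectors::mcols(seg)$protein_id
    pid <- if (!is.null(pid) && !is.na(pid[1L])) as.character(pid[1L]) else gid
    geneModel(gene_id = gid, species = species,
              chromosome = as.character(GenomicRanges::seqnames(seg))[1L],
              strand = strand, cds = m, protein_id = pid)
  })
  if (length(bad))
    stop("CDS length not divisible by 3 for gene(s): ",
         paste(bad, collapse = ", "))
  names(models) <- names(pick)
  models
}

#' Write gene models to a GFF3 file
#'
#' Emits a gene/mRNA/CDS hierarchy readable by [readGeneModels()];
#' internal 0-based half-open coordinates are converted back to the GFF3
#' 1-based inclusive convention (the conversion is an involution).
#'
#' @param models list of [GeneModel-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @importFrom GenomicRanges GRanges
#' @importFrom IRanges IRanges
#' @export
writeGeneModels <- function(models, path) {
  rows <- lapply(models, function(m) {
    cds <- cdsSegments(m)
    g <- cds[order(cds[, 1L]), , drop = FALSE]
    tx <- paste0(geneId(m), ".t1")
    data.frame(
      seqnames = m@chromosome,
      start = c(min(g[, 1L]) + 1L, min(g[, 1L]) + 1L, g[, 1L] + 1L),
      end = c(max(g[, 2L]), max(g[, 2L]), g[, 2L]),
      strand = m@strand,
      type = c("gene", "mRNA", rep("CDS", nrow(g))),
      ID = c(geneId(m), tx, paste0(tx, ".cds", seq_len(nrow(g)))),
      Parent = c(NA, geneId(m), rep(tx, nrow(g))),
      protein_id = c(NA, NA, rep(proteinId(m), nrow(g))),
      phase = c(NA, NA, .cdsPhases(m)[order(cds[, 1L])]),
      stringsAsFactors = FALSE
    )
  })
  df <- do.call(rbind, rows)
  gr <- GenomicRanges::GRanges(
    seqnames = df$seqnames,
    ranges = IRanges::IRanges(start = df$start, end = df$end),
    strand = df$strand,
    type = df$type, ID = df$ID, phase = df$phase,
    protein_id = df$protein_id
  )
  parent <- ifelse(is.na(df$Parent), "", df$Parent)
  S4Vectors::mcols(gr)$Parent <- S4Vectors::splitAsList(
    parent[nzchar(parent)],
    factor(seq_along(parent)[nzchar(parent)], levels = seq_along(parent)))
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

# GFF3 phase column (nt to skip to reach a codon start), per CDS segment
# in transcription order.
.cdsPhases <- function(model) {
  lens <- model@cds[, 2L] - model@cds[, 1L]
  before <- c(0L, cumsum(lens)[-length(lens)])
  as.integer((3L - before %% 3L) %% 3L)
}
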