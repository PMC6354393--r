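#' @import methods
#' @importFrom S4Vectors isSorted
NULL

#' GeneModel: one gene's coding exon structure
#'
#' A `GeneModel` holds the CDS segments of a single transcript on one
#' chromosome. Coordinates are stored 0-based, half-open, and segments are
#' kept in transcription order (5' to 3' of the mRNA), so that intron
#' positions can be computed without further strand handling. GFF3 I/O
#' converts to and from the 1-based inclusive convention of that format.
#'
#' @slot gene_id gene identifier.
#' @slot species species identifier.
#' @slot chromosome chromosome / scaffold name.
#' @slot strand `"+"` or `"-"`.
#' @slot cds integer matrix with columns `start`, `end` (0-based half-open),
#'   one row per CDS segment, in transcription order.
#' @slot protein_id identifier linking the model to a row of a protein
#'   alignment.
#'
#' @seealso [geneModel()], [readGeneModels()], [projectIntrons()]
#' @export
setClass("GeneModel",
  representation(
    gene_id = "character",
    species = "character",
    chromosome = "character",
    strand = "character",
    cds = "matrix",
    protein_id = "character"
  )
)

setValidity("GeneModel", function(object) {
  msg <- character()
  cds <- object@cds
  if (!is.numeric(cds) || ncol(cds) != 2L)
    return("cds must be a numeric matrix with columns start, end")
  if (nrow(cds) < 1L)
    msg <- c(msg, "at least one CDS segment is required")
  if (!object@strand %in% c("+", "-"))
    msg <- c(msg, "strand must be '+' or '-'")
  if (any(cds[, 2L] <= cds[, 1L]))
    msg <- c(msg, "every CDS segment must satisfy start < end")
  if (nrow(cds) > 1L) {
    # transcription order: ascending genomic on +, descending on -
    starts <- cds[, 1L]
    ordered <- if (object@strand == "+") !is.unsorted(starts, strictly = TRUE)
               else !is.unsorted(rev(starts), strictly = TRUE)
    if (!ordered)
      msg <- c(msg, "CDS segments must be in transcription order")
    gs <- cds[order(cds[, 1L]), , drop = FALSE]
    if (any(gs[-1L, 1L] < gs[-nrow(gs), 2L]))
      msg <- c(msg, "CDS segments must not overlap")
  }
  if (sum(cds[, 2L] - cds[, 1L]) %% 3L != 0L)
    msg <- c(msg, sprintf("total CDS length of '%s' is not divisible by 3",
                          object@gene_id))
  if (length(msg)) msg else TRUE
})

#' Construct a GeneModel
#'
#' @param gene_id,species,chromosome,strand,protein_id scalar character
#'   fields; `protein_id` defaults to `gene_id`.
#' @param cds two-column matrix (or data.frame) of 0-based half-open
#'   `start`, `end` CDS segments in transcription order.
#' @return A validated [GeneModel-class] object.
#' @examples
#' gm <- geneModel("g1", cds = cbind(0, 300))
#' cdsLength(gm)
#' @export
geneModel <- function(gene_id, species = "unknown", chromosome = gene_id,
                      strand = "+", cds, protein_id = gene_id) {
  cds <- as.matrix(cds)
  storage.mode(cds) <- "integer"
  colnames(cds) <- c("start", "end")
  new("GeneModel", gene_id = gene_id, species = species,
      chromosome = chromosome, strand = strand, cds = cds,
      protein_id = protein_id)
}

#' ProteinAlignment: an aligned set of protein sequences
#'
#' Thin wrapper around [Biostrings::AAStringSet] that enforces equal row
#' widths (i.e. the set is a multiple sequence alignment). Gaps are `-`.
#'
#' @seealso [readProteinAlignment()]
#' @importClassesFrom Biostrings AAStringSet
#' @export
setClass("ProteinAlignment", contains = "AAStringSet")

setValidity("ProteinAlignment", function(object) {
  w <- Biostrings::width(object)
  if (length(w) && length(unique(w)) != 1L) {
    bad <- names(object)[w != w[1L]]
    return(sprintf("alignment rows differ in length (e.g. '%s')", bad[1L]))
  }
  if (is.null(names(object)) || anyDuplicated(names(object)))
    return("alignment rows must carry unique names")
  TRUE
})

#' GenomeTable: per-species gene coordinates and family assignments
#'
#' The substrate of the conserved-synteny analysis: one record per gene with
#' its species, gene-family membership and chromosomal location (1-based
#' inclusive coordinates, as in the TSV interchange format).
#'
#' @slot records data.frame with columns `species`, `gene_id`, `family_id`,
#'   `chromosome`, `start`, `end`, `strand`.
#' @seealso [readGenomeTable()], [extractNeighbors()]
#' @export
setClass("GenomeTable", representation(records = "data.frame"))

.genomeTableCols <- c("species", "gene_id", "family_id", "chromosome",
                      "start", "end", "strand")

setValidity("GenomeTable", function(object) {
  rec <- object@records
  msg <- character()
  if (!all(.genomeTableCols %in% colnames(rec)))
    return(sprintf("records must contain columns: %s",
                   paste(.genomeTableCols, collapse = ", ")))
  key <- paste(rec$species, rec$gene_id)
  if (anyDuplicated(key))
    msg <- c(msg, sprintf("duplicate (species, gene_id): %s",
                          paste(unique(key[duplicated(key)]), collapse = ", ")))
  bad <- rec$start >= rec$end
  if (any(bad))
    msg <- c(msg, sprintf("start >= end for gene(s): %s",
                          paste(rec$gene_id[bad], collapse = ", ")))
  if (length(msg)) msg else TRUE
})

#' Construct a GenomeTable
#'
#' @param records data.frame with the seven required columns (see
#'   [GenomeTable-class]).
#' @return A validated [GenomeTable-class].
#' @export
genomeTable <- function(records) {
  records <- as.data.frame(records)
  records$start <- as.integer(records$start)
  records$end <- as.integer(records$end)
  rownames(records) <- NULL
  new("GenomeTable", records = records[, .genomeTableCols])
}

#' Paralogon: a set of related chromosome regions attributed to WGD
#'
#' A paralogon is a set of chromosomal regions of one species that share
#' members of multiple gene families as a result of chromosome (or whole
#' genome) duplication.
#'
#' @slot paralogon_id integer id.
#' @slot species focal species.
#' @slot regions character vector of chromosome names (>= 2).
#' @slot support data.frame, one row per supporting family: `family_id`,
#'   `n_regions` (regions of this paralogon it occupies), `pattern`
#'   (comma-separated occupied regions).
#' @slot completeness named integer vector: how many supporting families
#'   occupy 4, 3, 2 of the regions.
#' @slot translocation_note character; non-empty when the component exceeded
#'   the expected region count and was split, the signature of a
#'   post-duplication translocation.
#' @seealso [detectParalogons()], [scoreParalogon()]
#' @export
setClass("Paralogon",
  representation(
    paralogon_id = "integer",
    species = "character",
    regions = "character",
    support = "data.frame",
    completeness = "integer",
    translocation_note = "character"
  )
)

setValidity("Paralogon", function(object) {
  if (length(object@regions) < 2L)
    return("a paralogon must span at least two regions")
  if (nrow(object@support) &&
      any(object@support$n_regions < 2L))
    return("every supporting family must occupy at least two regions")
  TRUE
})

#' Repertoire: a gene repertoire at a node of the species tree
#'
#' Tracks the gene list at one lineage/node together with a ledger of the
#' loss and gain events along the edge leading to it, so that the identity
#' count = parent count - losses + gains can be asserted at every step.
#'
#' @slot label lineage or tree-node label.
#' @slot genes character vector of gene names present.
#' @slot ledger data.frame of events: `event` (`"loss"`, `"gain"`,
#'   `"wgd_duplicate"`), `gene`, `unconfirmed` (logical; a gene not
#'   identified in an assembly is counted as lost but flagged, since it may
#'   reside on unsequenced sequence such as GC-rich microchromosomes).
#' @seealso [repertoire()], [lineageRepertoire()], [applyWGD()]
#' @export
setClass("Repertoire",
  representation(
    label = "character",
    genes = "character",
    ledger = "data.frame"
  )
)

setValidity("Repertoire", function(object) {
  if (anyDuplicated(object@genes))
    return(sprintf("duplicate gene names: %s",
                   paste(unique(object@genes[duplicated(object@genes)]),
                         collapse = ", ")))
  TRUE
})

#' Construct a Repertoire
#'
#' @param label node label.
#' @param genes character vector of genes present at the node.
#' @param ledger optional event ledger (default empty).
#' @return A [Repertoire-class] object.
#' @examples
#' r <- repertoire("vertebrate_post2R", c("A", "B", "C"))
#' repertoireCount(r)
#' @export
repertoire <- function(label, genes, ledger = NULL) {
  if (is.null(ledger))
    ledger <- data.frame(event = character(), gene = character(),
                         unconfirmed = logical())
  new("Repertoire", label = label, genes = as.character(genes),
      ledger = ledger)
}
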