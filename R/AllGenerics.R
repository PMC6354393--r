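#' Accessors for package classes
#'
#' Small accessor generics so that slots are never reached into directly.
#'
#' @param x an object of the documented class.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("geneId", function(x) standardGeneric("geneId"))
#' @rdname accessors
#' @export
setGeneric("proteinId", function(x) standardGeneric("proteinId"))
#' @rdname accessors
#' @export
setGeneric("cdsSegments", function(x) standardGeneric("cdsSegments"))
#' @rdname accessors
#' @export
setGeneric("cdsLength", function(x) standardGeneric("cdsLength"))
#' @rdname accessors
#' @export
setGeneric("proteinLength", function(x) standardGeneric("proteinLength"))
#' @rdname accessors
#' @export
setGeneric("regions", function(x) standardGeneric("regions"))
#' @rdname accessors
#' @export
setGeneric("supportTable", function(x) standardGeneric("supportTable"))
#' @rdname accessors
#' @export
setGeneric("completeness", function(x) standardGeneric("completeness"))
#' @rdname accessors
#' @export
setGeneric("repertoireGenes", function(x) standardGeneric("repertoireGenes"))
#' @rdname accessors
#' @export
setGeneric("repertoireCount", function(x) standardGeneric("repertoireCount"))
#' @rdname accessors
#' @export
setGeneric("eventLedger", function(x) standardGeneric("eventLedger"))

#' @rdname accessors
#' @export
setMethod("geneId", "GeneModel", function(x) x@gene_id)
#' @rdname accessors
#' @export
setMethod("proteinId", "GeneModel", function(x) x@protein_id)
#' @rdname accessors
#' @export
setMethod("cdsSegments", "GeneModel", function(x) x@cds)
#' @rdname accessors
#' @export
setMethod("cdsLength", "GeneModel",
          function(x) sum(x@cds[, 2L] - x@cds[, 1L]))
#' @rdname accessors
#' @export
setMethod("proteinLength", "GeneModel",
          function(x) cdsLength(x) %/% 3L - 1L)

#' @rdname accessors
#' @export
setMethod("regions", "Paralogon", function(x) x@regions)
#' @rdname accessors
#' @export
setMethod("supportTable", "Paralogon", function(x) x@support)
#' @rdname accessors
#' @export
setMethod("completeness", "Paralogon", function(x) x@completeness)

#' @rdname accessors
#' @export
setMethod("repertoireGenes", "Repertoire", function(x) x@genes)
#' @rdname accessors
#' @export
setMethod("repertoireCount", "Repertoire", function(x) length(x@genes))
#' @rdname accessors
#' @export
setMethod("eventLedger", "Repertoire", function(x) x@ledger)

#' @rdname accessors
#' @param object object to display.
#' @export
setMethod("show", "GeneModel", function(object) {
  cat(sprintf("GeneModel '%s' (%s) %s:%s [%d CDS segment%s, %d aa]\n",
              object@gene_id, object@species, object@chromosome,
              object@strand, nrow(object@cds),
              if (nrow(object@cds) == 1L) "" else "s",
              proteinLength(object)))
})

#' @rdname accessors
#' @export
setMethod("show", "GenomeTable", function(object) {
  rec <- object@records
  cat(sprintf("GenomeTable: %d genes, %d species, %d families\n",
              nrow(rec), length(unique(rec$species)),
              length(unique(rec$family_id))))
})

#' @rdname accessors
#' @export
setMethod("show", "Paralogon", function(object) {
  cat(sprintf("Paralogon %d (%s): regions {%s}, %d supporting families%s\n",
              object@paralogon_id, object@species,
              paste(object@regions, collapse = ", "),
              nrow(object@support),
              if (length(object@translocation_note) &&
                  nzchar(object@translocation_note[1L]))
                " [translocation split]" else ""))
})

#' @rdname accessors
#' @export
setMethod("show", "Repertoire", function(object) {
  cat(sprintf("Repertoire '%s': %d genes (%d ledger events)\n",
              object@label, length(object@genes), nrow(object@ledger)))
})

#' @rdname accessors
#' @export
setMethod("as.data.frame", "GenomeTable",
          function(x, row.names = NULL, optional = FALSE, ...) x@records)
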