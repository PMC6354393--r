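#' Read an aligned protein FASTA
#'
#' @param path path to an aligned FASTA file (gap character `-`).
#' @return A [ProteinAlignment-class]; an error names the first offending
#'   header if rows are ragged.
#' @examples
#' f <- tempfile(fileext = ".fa")
#' writeLines(c(">a", "MK-V", ">b", "MKLV"), f)
#' aln <- readProteinAlignment(f)
#' @importFrom Biostrings readAAStringSet
#' @export
readProteinAlignment <- function(path) {
  x <- Biostrings::readAAStringSet(path)
  w <- Biostrings::width(x)
  if (length(unique(w)) > 1L)
    stop(sprintf("alignment rows are ragged: '%s' has %d columns, expected %d",
                 names(x)[which(w != w[1L])[1L]], w[w != w[1L]][1L], w[1L]))
  new("ProteinAlignment", x)
}

#' Write an aligned protein FASTA
#'
#' @param aln a [ProteinAlignment-class] (or AAStringSet).
#' @param path output path.
#' @return `path`, invisibly.
#' @importFrom Biostrings writeXStringSet
#' @export
writeProteinAlignment <- function(aln, path) {
  Biostrings::writeXStringSet(aln, path)
  invisible(path)
}

#' Read a guide tree from a Newick file
#'
#' The guide tree is a fixed, externally inferred gene (or species) tree on
#' which intron gains and losses are reconstructed. Polytomies are
#' preserved; duplicate leaf labels are rejected.
#'
#' @param path path to a Newick file.
#' @param rooted require the tree to be rooted (default TRUE).
#' @return An [ape::phylo] tree.
#' @importFrom ape read.tree is.rooted
#' @export
readGuideTree <- function(path, rooted = TRUE) {
  tree <- ape::read.tree(path)
  if (is.null(tree)) stop("could not parse Newick file '", path, "'")
  dup <- unique(tree$tip.label[duplicated(tree$tip.label)])
  if (length(dup))
    stop("duplicate leaf labels in tree: ", paste(dup, collapse = ", "))
  if (rooted && !ape::is.rooted(tree))
    stop("tree in '", path, "' is unrooted but a rooted tree is required")
  tree
}

#' Read a genome table from TSV
#'
#' Expects a header with the seven columns `species gene_id family_id
#' chromosome start end strand` (1-based inclusive coordinates).
#'
#' @param path path to a tab-separated file.
#' @return A validated [GenomeTable-class].
#' @importFrom utils read.delim
#' @export
readGenomeTable <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  missing <- setdiff(.genomeTableCols, colnames(df))
  if (length(missing))
    stop("genome table '", path, "' lacks column(s): ",
         paste(missing, collapse = ", "))
  genomeTable(df)
}

#' Write a genome table to TSV
#'
#' @param table a [GenomeTable-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @importFrom utils write.table
#' @export
writeGenomeTable <- function(table, path) {
  utils::write.table(as.data.frame(table), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read family curation flags from TSV
#'
#' Neighbour gene families enter the synteny analysis only after manual
#' curation of their trees; the four judgement flags are consumed from a
#' TSV (`family_id clear_topology strong_support has_outgroup
#' low_conservation`), they are never computed here.
#'
#' @param path path to a tab-separated file.
#' @return data.frame with logical flag columns.
#' @export
readCurationFlags <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("family_id", "clear_topology", "strong_support",
            "has_outgroup", "low_conservation")
  missing <- setdiff(need, colnames(df))
  if (length(missing))
    stop("curation table '", path, "' lacks column(s): ",
         paste(missing, collapse = ", "))
  for (col in need[-1L]) df[[col]] <- as.logical(df[[col]])
  df
}
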