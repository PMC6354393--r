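#' The packaged nAChR gene-family fixture
#'
#' A compact, text-encoded rendering of the vertebrate nicotinic
#' acetylcholine receptor (nAChR) dataset: 10 ohnolog groups covering the
#' 19 post-2R subunit genes, per-lineage loss/gain ledgers, the intron
#' presence sets of the four exon-intron gene groups (20 intron clusters),
#' and the guide-tree topology. Gene structures are synthetic: exon sizes
#' are chosen so that projecting the emitted GFF3 models onto the emitted
#' alignment reproduces the intron matrix exactly, with the published
#' intron numbering carried as a column/phase map (cluster 17 sits one
#' codon from cluster 12 at the same phase — the documented near miss).
#'
#' @return list with components `ohnolog_groups` (data.frame `group_id`,
#'   `gene_id`, `tandem_parent`), `genes` (the 19 post-2R genes),
#'   `lineages` (data.frame `lineage`, `event`, `gene`, `unconfirmed`),
#'   `retained_3R` / `retained_3R_zebrafish` (character vectors),
#'   `intron_sets` (named list: gene -> published cluster ids),
#'   `cluster_map` (data.frame `published_id`, `column`, `phase`),
#'   `exon_intron_groups` (named list of 4 gene sets),
#'   `tree_text` (Newick), `protein_length`.
#' @examples
#' fx <- nachrFixture()
#' length(unique(fx$ohnolog_groups$group_id))  # 10
#' @export
nachrFixture <- function() {
  grp <- function(id, genes, parent = NA_character_)
    data.frame(group_id = id, gene_id = genes, tandem_parent = parent)
  ohnolog_groups <- rbind(
    grp("A9-A10",    c("CHRNA9", "CHRNA10")),
    grp("A7-A8-A11", c("CHRNA7", "CHRNA8", "CHRNA11")),
    grp("B2-B4-B5",  c("CHRNB2", "CHRNB4", "CHRNB5"), "neuronal-cluster"),
    grp("B1",        "CHRNB1",                        "NMJ-nonalpha"),
    grp("D",         "CHRND",                         "NMJ-nonalpha"),
    grp("E-G",       c("CHRNE", "CHRNG"),             "NMJ-nonalpha"),
    grp("A1",        "CHRNA1"),
    grp("A5-B3",     c("CHRNA5", "CHRNB3"),           "neuronal-cluster"),
    grp("A3-A6",     c("CHRNA3", "CHRNA6"),           "neuronal-cluster"),
    grp("A2-A4",     c("CHRNA2", "CHRNA4")))
  genes <- ohnolog_groups$gene_id

  ev <- function(lineage, event, gene, unconfirmed = FALSE)
    data.frame(lineage = lineage, event = event, gene = gene,
               unconfirmed = unconfirmed)
  lineages <- rbind(
    ev("human",   "loss", c("CHRNA8", "CHRNA11", "CHRNB5")),
    ev("chicken", "loss", c("CHRNA11", "CHRNB5")),
    ev("chicken", "loss", c("CHRNB1", "CHRNE"), unconfirmed = TRUE),
    ev("spotted_gar", "loss", "CHRNB2", unconfirmed = TRUE),
    ev("spotted_gar", "gain", "CHRNB1.2"),
    ev("teleost_predecessor", "gain", "CHRNB1.2"),
    ev("medaka", "loss", "CHRNG", unconfirmed = TRUE),
    ev("stickleback", "loss", "CHRND", unconfirmed = TRUE))

  retained_3R <- c("CHRNA9", "CHRNA10", "CHRNA7", "CHRNA8", "CHRNA11",
                   "CHRNB5", "CHRNA1", "CHRNA2", "CHRNA4", "CHRNA6",
                   "CHRNB3")
  retained_3R_zebrafish <- c("CHRNA2", "CHRNA4", "CHRNA7", "CHRNA9",
                             "CHRNA10", "CHRNB5", "CHRNB3")

  intron_sets <- list(
    CHRNA9  = 1:4, CHRNA10 = 1:4,
    CHRNA7  = 1:9, CHRNA8 = 1:9, CHRNA11 = 1:9,
    CHRNB1  = c(1:3, 5L, 10:15), CHRNB1.2 = c(1:3, 5L, 10:15),
    CHRND   = c(1:3, 5L, 11L, 13L, 15L, 16:19),
    CHRNE   = c(1:3, 5L, 11L, 13L, 15L, 16:19),
    CHRNG   = c(1:3, 5L, 11L, 13L, 15L, 16:19),
    CHRNA1  = c(1:3, 5L, 12L, 13L, 15L, 20L))
  neuronal <- c("CHRNA2", "CHRNA3", "CHRNA4", "CHRNA5", "CHRNA6",
                "CHRNB2", "CHRNB3", "CHRNB4", "CHRNB5")
  for (g in neuronal) intron_sets[[g]] <- c(1:3, 5L, 15L)

  # published numbering vs alignment order: published cluster 17 lies one
  # codon after published 12, so positional (column) order interleaves it
  positional <- c(1:12, 17, 13, 14, 15, 16, 18, 19, 20)
  column <- 22L * seq_along(positional)
  column[positional == 17] <- column[positional == 12] + 1L
  cluster_map <- data.frame(published_id = positional, column = column,
                            phase = 0L)
  cluster_map <- cluster_map[order(cluster_map$published_id), ]
  rownames(cluster_map) <- NULL

  exon_intron_groups <- list(
    A9_A10 = c("CHRNA9", "CHRNA10"),
    A7_A8_A11 = c("CHRNA7", "CHRNA8", "CHRNA11"),
    NMJ = c("CHRNB1", "CHRNB1.2", "CHRND", "CHRNE", "CHRNG", "CHRNA1"),
    neuronal = neuronal)

  tree_text <- paste0(
    "((CHRNA9,CHRNA10)A9A10,((CHRNA7,CHRNA8,CHRNA11)A7A8A11,",
    "((((CHRNB1,CHRNB1.2)B1pair,(CHRND,(CHRNE,CHRNG)EG)DEG)NMJnonalpha,",
    "(CHRNB2,CHRNB4,CHRNB5)B2B4B5)Bclade,",
    "(CHRNA1,((CHRNA5,CHRNB3)A5B3,(CHRNA3,CHRNA6)A3A6,",
    "(CHRNA2,CHRNA4)A2A4)neuronalAlpha)alphaClade)restAncestor)",
    "postA9A10)nachrRoot;")

  list(ohnolog_groups = ohnolog_groups, genes = genes,
       lineages = lineages, retained_3R = retained_3R,
       retained_3R_zebrafish = retained_3R_zebrafish,
       intron_sets = intron_sets, cluster_map = cluster_map,
       exon_intron_groups = exon_intron_groups,
       tree_text = tree_text, protein_length = 460L)
}

# the shared synthetic protein of the fixture alignment (gap-free)
.fixtureProtein <- function(L = 460L) {
  base <- strrep("ACDEFGHIKLMNPQRSTVWY", ceiling(L / 20))
  substr(base, 1L, L)
}

# synthetic gene model whose CDS breakpoints realise the given published
# intron clusters (intron length 200 bp, gene offset 1000)
.fixtureGeneModel <- function(gene, published_ids, cluster_map, L,
                              strand = "+") {
  cm <- cluster_map[match(published_ids, cluster_map$published_id), ]
  nts <- sort(3L * cm$column + cm$phase)
  total <- 3L * (L + 1L)
  bounds <- c(0L, nts, total)
  lens <- diff(bounds)
  intron <- 200L
  if (strand == "+") {
    starts <- 1000L + cumsum(c(0L, head(lens, -1L) + intron))
    cds <- cbind(start = starts, end = starts + lens)
  } else {
    # transcription order runs right-to-left on the genome
    span <- sum(lens) + intron * (length(lens) - 1L)
    ends <- 1000L + span - cumsum(c(0L, head(lens, -1L) + intron))
    cds <- cbind(start = ends - lens, end = ends)
  }
  geneModel(gene, species = "fixture",
            chromosome = paste0("chr_", gene), strand = strand, cds = cds)
}

#' Build the fixture gene models and alignment in memory
#'
#' @param fx fixture list from [nachrFixture()].
#' @return list with `models` (named list of [GeneModel-class], one per
#'   gene incl. the CHRNB1.2 local duplicate) and `alignment`
#'   ([ProteinAlignment-class], gap-free).
#' @export
nachrGeneModels <- function(fx = nachrFixture()) {
  L <- fx$protein_length
  ids <- names(fx$intron_sets)
  models <- lapply(ids, function(g)
    .fixtureGeneModel(g, fx$intron_sets[[g]], fx$cluster_map, L,
                      strand = if (g %in% c("CHRNB1.2", "CHRNG")) "-" else "+"))
  names(models) <- ids
  seqs <- Biostrings::AAStringSet(setNames(rep(.fixtureProtein(L),
                                               length(ids)), ids))
  list(models = models, alignment = new("ProteinAlignment", seqs))
}

#' Write the fixture to disk
#'
#' Emits every file of the packaged dataset in the package's interchange
#' formats: `ohnolog_groups.tsv`, `lineage_ledger.tsv`,
#' `intron_matrix.tsv` (1/0 cells, columns in the published numbering),
#' `cluster_numbering.tsv`, `guide_tree.nwk`, `gene_models.gff3` and
#' `alignment.fasta`. Re-reading the GFF3 and FASTA through the package
#' and projecting reproduces the matrix exactly.
#'
#' @param outdir output directory (created if needed).
#' @return named list of the file paths written, invisibly.
#' @export
writeFixture <- function(outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  fx <- nachrFixture()
  gm <- nachrGeneModels(fx)
  paths <- list(
    ohnolog = file.path(outdir, "ohnolog_groups.tsv"),
    ledger = file.path(outdir, "lineage_ledger.tsv"),
    matrix = file.path(outdir, "intron_matrix.tsv"),
    numbering = file.path(outdir, "cluster_numbering.tsv"),
    tree = file.path(outdir, "guide_tree.nwk"),
    gff3 = file.path(outdir, "gene_models.gff3"),
    fasta = file.path(outdir, "alignment.fasta"))
  utils::write.table(fx$ohnolog_groups, paths$ohnolog, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(fx$lineages, paths$ledger, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  mat <- matrix(0L, length(fx$intron_sets), 20L,
                dimnames = list(names(fx$intron_sets), as.character(1:20)))
  for (g in names(fx$intron_sets)) mat[g, fx$intron_sets[[g]]] <- 1L
  utils::write.table(cbind(gene_id = rownames(mat), as.data.frame(mat)),
                     paths$matrix, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(fx$cluster_map, paths$numbering, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  writeLines(fx$tree_text, paths$tree)
  writeGeneModels(gm$models, paths$gff3)
  writeProteinAlignment(gm$alignment, paths$fasta)
  invisible(paths)
}

#' Relabel presence-matrix columns with the published intron numbering
#'
#' Clustering assigns ids in ascending column order; the published
#' numbering of the fixture interleaves cluster 17 between 12 and 13
#' (it sits one codon after 12). This renames matrix columns by matching
#' each cluster's (column, phase) against the numbering map.
#'
#' @param matrix presence matrix from [buildPresenceMatrix()].
#' @param clusters the `clusters` data.frame from [clusterIntronSites()].
#' @param cluster_map data.frame `published_id`, `column`, `phase` (see
#'   [nachrFixture()]).
#' @return the matrix with renamed (and re-ordered, ascending published
#'   id) columns.
#' @export
applyClusterNumbering <- function(matrix, clusters, cluster_map) {
  key <- match(
    paste(clusters$column, clusters$phase),
    paste(cluster_map$column, cluster_map$phase))
  if (anyNA(key))
    stop("cluster(s) missing from the numbering map at column(s): ",
         paste(clusters$column[is.na(key)], collapse = ", "))
  pub <- cluster_map$published_id[key]
  colnames(matrix) <- as.character(
    pub[match(colnames(matrix), as.character(clusters$cluster_id))])
  matrix[, order(as.integer(colnames(matrix))), drop = FALSE]
}
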