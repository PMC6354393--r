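#' Project intron positions onto a protein alignment
#'
#' Each CDS-internal intron of a gene model is expressed in protein
#' coordinates and then mapped to an alignment column by walking the gapped
#' row of that gene's protein. The splice phase is the number of
#' nucleotides of the interrupted codon lying 5' of the intron (0 = the
#' intron falls between codons); `residue_index` is the 0-based index of
#' the residue whose codon the intron precedes (phase 0) or interrupts
#' (phase 1/2).
#'
#' @param model a [GeneModel-class] whose `protein_id` is a row of `aln`.
#' @param aln a [ProteinAlignment-class].
#' @return data.frame with one row per intron: `gene_id`, `protein_id`,
#'   `residue_index`, `phase`, `column` (0-based alignment column).
#'   Intron-less genes yield zero rows.
#' @examples
#' gm <- geneModel("g", cds = rbind(c(0, 100), c(200, 400)))
#' aln <- new("ProteinAlignment",
#'            Biostrings::AAStringSet(c(g = strrep("A", 99))))
#' projectIntrons(gm, aln)  # phase 1 at residue 33
#' @export
projectIntrons <- function(model, aln) {
  pid <- proteinId(model)
  if (!pid %in% names(aln))
    stop("protein '", pid, "' of gene '", geneId(model),
         "' is not a row of the alignment")
  row <- strsplit(as.character(aln[[pid]]), "")[[1L]]
  res_cols <- which(row != "-") - 1L          # 0-based column per residue
  L <- length(res_cols)
  if (proteinLength(model) != L)
    stop(sprintf(
      "gene '%s': CDS implies %d residues but alignment row '%s' has %d",
      geneId(model), proteinLength(model), pid, L))

  lens <- cdsSegments(model)[, 2L] - cdsSegments(model)[, 1L]
  if (length(lens) == 1L)
    return(data.frame(gene_id = character(), protein_id = character(),
                      residue_index = integer(), phase = integer(),
                      column = integer()))
  nt_before <- cumsum(lens)[-length(lens)]   # CDS nt 5' of each intron
  if (any(nt_before > 3L * L))
    stop("gene '", geneId(model), "': intron falls inside the stop codon")
  phase <- as.integer(nt_before %% 3L)
  residue <- as.integer(nt_before %/% 3L)
  column <- ifelse(residue >= L, max(res_cols) + 1L, res_cols[residue + 1L])
  data.frame(gene_id = geneId(model), protein_id = pid,
             residue_index = residue, phase = phase,
             column = as.integer(column))
}

#' Cluster homologous intron sites
#'
#' Intron sites projected onto one alignment are clustered by exact match
#' of (alignment column, splice phase): two introns are called homologous
#' only when both agree. Site pairs with the same phase whose columns
#' differ by at most `shift_tolerance` codons are *not* merged but reported
#' as near misses, so that possible one-codon intron shifts can be
#' inspected rather than silently combined.
#'
#' @param sites data.frame of intron sites as produced by
#'   [projectIntrons()] (rows from several genes concatenated).
#' @param shift_tolerance maximum codon shift (alignment columns) reported
#'   as a near miss; default 1.
#' @return list with elements `clusters` (data.frame `cluster_id`, `column`,
#'   `phase`, `n_members`; ids ascend by column, ties by phase), `sites`
#'   (input plus `cluster_id`), and `near_misses` (data.frame of unmerged
#'   same-phase cluster pairs with their codon shift).
#' @export
clusterIntronSites <- function(sites, shift_tolerance = 1L) {
  empty <- list(
    clusters = data.frame(cluster_id = integer(), column = integer(),
                          phase = integer(), n_members = integer()),
    sites = cbind(sites, cluster_id = integer(nrow(sites))),
    near_misses = data.frame(cluster_a = integer(), cluster_b = integer(),
                             column_a = integer(), column_b = integer(),
                             phase = integer(), codon_shift = integer()))
  if (nrow(sites) == 0L) return(empty)

  key <- unique(sites[, c("column", "phase")])
  key <- key[order(key$column, key$phase), , drop = FALSE]
  key$cluster_id <- seq_len(nrow(key))
  sites <- merge(sites, key, by = c("column", "phase"), sort = FALSE)
  n <- as.integer(table(factor(sites$cluster_id, levels = key$cluster_id)))
  clusters <- data.frame(cluster_id = key$cluster_id, column = key$column,
                         phase = key$phase, n_members = n)

  nm <- list()
  for (i in seq_len(nrow(clusters) - 1L)) for (j in seq(i + 1L, nrow(clusters))) {
    if (j > nrow(clusters)) break
    shift <- abs(clusters$column[j] - clusters$column[i])
    if (clusters$phase[i] == clusters$phase[j] &&
        shift >= 1L && shift <= shift_tolerance)
      nm[[length(nm) + 1L]] <- data.frame(
        cluster_a = clusters$cluster_id[i], cluster_b = clusters$cluster_id[j],
        column_a = clusters$column[i], column_b = clusters$column[j],
        phase = clusters$phase[i], codon_shift = as.integer(shift))
  }
  near <- if (length(nm)) do.call(rbind, nm) else empty$near_misses
  ord <- order(sites$cluster_id, sites$gene_id)
  list(clusters = clusters,
       sites = sites[ord, c("gene_id", "protein_id", "residue_index",
                            "phase", "column", "cluster_id")],
       near_misses = near)
}

#' Build a gene-by-cluster intron presence matrix
#'
#' @param clustering result of [clusterIntronSites()].
#' @param genes character vector of gene ids wanted as rows (supersets of
#'   the genes with sites are allowed; genes without any site get an
#'   all-absent row).
#' @param partial_genes genes with incomplete models: their absences are
#'   recorded as unknown (`NA`) rather than absent.
#' @param alignment optional [ProteinAlignment-class]; when supplied every
#'   gene must correspond to a row (by gene or protein id), otherwise an
#'   error is raised.
#' @return integer matrix (1 present, 0 absent, `NA` unknown) with genes as
#'   rows and cluster ids as columns.
#' @export
buildPresenceMatrix <- function(clustering, genes, partial_genes = character(),
                                alignment = NULL) {
  if (!is.null(alignment)) {
    known <- c(names(alignment),
               unique(clustering$sites$gene_id))
    miss <- setdiff(genes, known)
    if (length(miss))
      stop("gene(s) not in alignment: ", paste(miss, collapse = ", "))
  }
  ids <- clustering$clusters$cluster_id
  mat <- matrix(0L, nrow = length(genes), ncol = length(ids),
                dimnames = list(genes, as.character(ids)))
  if (length(partial_genes))
    mat[intersect(partial_genes, genes), ] <- NA_integer_
  s <- clustering$sites
  s <- s[s$gene_id %in% genes, , drop = FALSE]
  mat[cbind(s$gene_id, as.character(s$cluster_id))] <- 1L
  mat
}

#' Count intron clusters shared within and between gene groups
#'
#' Summarises an intron presence matrix against a partition of its genes
#' into exon-intron groups: for each cluster, how many groups contain it;
#' overall, how many clusters are present in every gene, shared by at least
#' two groups, or confined to a single group.
#'
#' @param matrix presence matrix from [buildPresenceMatrix()].
#' @param gene_groups named list of character vectors partitioning the
#'   matrix rows.
#' @return list with `per_cluster` (data.frame `cluster_id`, `n_groups`,
#'   `in_all_genes`) and `summary` (named integer vector `all_genes`,
#'   `multi_group`, `single_group`).
#' @export
countSharedIntrons <- function(matrix, gene_groups) {
  rows <- unlist(gene_groups, use.names = FALSE)
  miss <- setdiff(rows, rownames(matrix))
  if (length(miss))
    stop("gene group(s) reference unknown row(s): ",
         paste(miss, collapse = ", "))
  n_groups <- vapply(colnames(matrix), function(cl) {
    sum(vapply(gene_groups, function(g)
      any(matrix[g, cl] %in% 1L), logical(1L)))
  }, integer(1L))
  in_all <- vapply(colnames(matrix), function(cl)
    all(matrix[rows, cl] %in% 1L), logical(1L))
  per <- data.frame(cluster_id = colnames(matrix),
                    n_groups = as.integer(n_groups),
                    in_all_genes = in_all, row.names = NULL)
  list(per_cluster = per,
       summary = c(all_genes = sum(in_all),
                   multi_group = sum(n_groups >= 2L),
                   single_group = sum(n_groups == 1L)))
}

#' Annotate cysteines, cysteine pairs and N-glycosylation sites
#'
#' Scans the ungapped sequence of each alignment row for single cysteines,
#' cysteine pairs (two cysteines at most `max_pair_sep` residues apart,
#' e.g. the adjacent pair characteristic of alpha subunits), and N-linked
#' glycosylation consensus motifs N-X-[S/T] with X != P. Positions are
#' reported as alignment columns so that "corresponding positions" across
#' genes are simply identical columns.
#'
#' @param aln a [ProteinAlignment-class].
#' @param gene_ids rows to annotate (default all).
#' @param max_pair_sep maximum residue-index difference for a cysteine
#'   pair; default 3.
#' @return data.frame `gene_id`, `kind` (`cysteine`, `cysteine_pair`,
#'   `n_glycosylation`), `column` (0-based; pair start), `column_end`
#'   (second cysteine of a pair, else `NA`).
#' @export
annotateMotifs <- function(aln, gene_ids = names(aln), max_pair_sep = 3L) {
  out <- list()
  for (id in gene_ids) {
    chars <- strsplit(as.character(aln[[id]]), "")[[1L]]
    res_cols <- which(chars != "-") - 1L
    seqv <- chars[chars != "-"]
    bad <- setdiff(unique(seqv), c(strsplit("ACDEFGHIKLMNPQRSTVWYX", "")[[1L]]))
    if (length(bad))
      stop("row '", id, "' contains non-amino-acid character(s): ",
           paste(bad, collapse = ", "))
    cys <- which(seqv == "C")
    for (i in cys)
      out[[length(out) + 1L]] <- data.frame(
        gene_id = id, kind = "cysteine",
        column = res_cols[i], column_end = NA_integer_)
    if (length(cys) >= 2L)
      for (k in seq_len(length(cys) - 1L))
        if (cys[k + 1L] - cys[k] <= max_pair_sep)
          out[[length(out) + 1L]] <- data.frame(
            gene_id = id, kind = "cysteine_pair",
            column = res_cols[cys[k]], column_end = res_cols[cys[k + 1L]])
    s <- paste(seqv, collapse = "")
    hits <- gregexpr("N(?=[^P][ST])", s, perl = TRUE)[[1L]]
    if (hits[1L] != -1L)
      for (p in as.integer(hits))
        out[[length(out) + 1L]] <- data.frame(
          gene_id = id, kind = "n_glycosylation",
          column = res_cols[p], column_end = NA_integer_)
  }
  if (!length(out))
    return(data.frame(gene_id = character(), kind = character(),
                      column = integer(), column_end = integer()))
  df <- do.call(rbind, out)
  rownames(df) <- NULL
  df
}
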