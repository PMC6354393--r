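#' Extract the neighbour window around an anchor gene
#'
#' Returns every gene of the anchor's species whose midpoint lies within
#' `window_bp` of the anchor midpoint (closed interval) on the anchor's
#' chromosome — the neighbourhood whose gene families feed the
#' conserved-synteny analysis. The default window of 10 Mb either side
#' matches the standard practice for paralogon screens.
#'
#' @param table a [GenomeTable-class].
#' @param anchor gene id of the anchor (must be present in the table).
#' @param window_bp half-width of the window in bp (default 1e7).
#' @return list with `anchor`, `species`, `chromosome`, `interval`
#'   (numeric length 2), and `members` (data.frame of gene records).
#' @export
extractNeighbors <- function(table, anchor, window_bp = 1e7) {
  stopifnot(window_bp > 0)
  rec <- as.data.frame(table)
  hit <- rec[rec$gene_id == anchor, , drop = FALSE]
  if (nrow(hit) == 0L) stop("anchor gene '", anchor, "' not in genome table")
  hit <- hit[1L, ]
  mid <- (hit$start + hit$end) / 2
  same <- rec[rec$species == hit$species &
              rec$chromosome == hit$chromosome, , drop = FALSE]
  mids <- (same$start + same$end) / 2
  members <- same[abs(mids - mid) <= window_bp, , drop = FALSE]
  rownames(members) <- NULL
  list(anchor = anchor, species = hit$species, chromosome = hit$chromosome,
       interval = c(mid - window_bp, mid + window_bp), members = members)
}

#' Filter candidate neighbour families by curation criteria
#'
#' A neighbour gene family is retained for paralogon analysis only when it
#' has at least `min_members` members in the focal species and all four
#' curation flags are favourable: a clear tree topology, strong node
#' support, an available outgroup and no excessive sequence conservation.
#' The flags come from a curation table ([readCurationFlags()]) — the
#' underlying tree inspection is manual and outside this package. When a
#' family carries no flags it is treated as favourable with a warning.
#'
#' @param table a [GenomeTable-class] (focal species only, or filtered).
#' @param species focal species.
#' @param flags data.frame of curation flags, or `NULL` (all favourable,
#'   with a warning).
#' @param min_members minimum family size in the focal species (default 2).
#' @return list with `retained` (character family ids) and `excluded`
#'   (data.frame `family_id`, `reason`).
#' @export
filterFamilies <- function(table, species, flags = NULL, min_members = 2L) {
  rec <- as.data.frame(table)
  rec <- rec[rec$species == species, , drop = FALSE]
  fams <- sort(unique(rec$family_id))
  if (is.null(flags)) {
    warning("no curation flags supplied; retaining all families")
    flags <- data.frame(family_id = fams, clear_topology = TRUE,
                        strong_support = TRUE, has_outgroup = TRUE,
                        low_conservation = FALSE)
  }
  sizes <- table(rec$family_id)
  reasons <- lapply(fams, function(f) {
    if (sizes[[f]] < min_members) return("min_members")
    fl <- flags[flags$family_id == f, , drop = FALSE]
    if (nrow(fl) == 0L) return(NA_character_)
    fl <- fl[1L, ]
    if (!isTRUE(fl$clear_topology)) return("topology")
    if (!isTRUE(fl$strong_support)) return("support")
    if (!isTRUE(fl$has_outgroup)) return("outgroup")
    if (isTRUE(fl$low_conservation)) return("conservation")
    NA_character_
  })
  reasons <- unlist(reasons)
  list(retained = fams[is.na(reasons)],
       excluded = data.frame(family_id = fams[!is.na(reasons)],
                             reason = reasons[!is.na(reasons)]))
}

#' Build the chromosome co-occurrence graph of neighbour families
#'
#' Nodes are chromosomes of the focal species; an edge joins two
#' chromosomes with weight equal to the number of retained families having
#' at least one member on each — the quantitative trace of a block
#' duplication.
#'
#' @param table a [GenomeTable-class].
#' @param species focal species.
#' @param families character vector of retained family ids.
#' @return an [igraph::igraph] weighted undirected graph (no self edges).
#' @importFrom igraph graph_from_data_frame make_empty_graph
#' @export
buildParalogonGraph <- function(table, species, families) {
  rec <- as.data.frame(table)
  rec <- rec[rec$species == species & rec$family_id %in% families, ,
             drop = FALSE]
  pairs <- list()
  for (f in unique(rec$family_id)) {
    chrs <- sort(unique(rec$chromosome[rec$family_id == f]))
    if (length(chrs) >= 2L) {
      cb <- utils::combn(chrs, 2L)
      pairs[[f]] <- data.frame(a = cb[1L, ], b = cb[2L, ], family = f)
    }
  }
  chrs_all <- sort(unique(rec$chromosome))
  if (!length(pairs)) {
    g <- igraph::make_empty_graph(n = length(chrs_all), directed = FALSE)
    g <- igraph::set_vertex_attr(g, "name", value = chrs_all)
    return(g)
  }
  df <- do.call(rbind, pairs)
  agg <- stats::aggregate(list(weight = rep(1L, nrow(df))),
                          by = list(a = df$a, b = df$b), FUN = sum)
  g <- igraph::graph_from_data_frame(agg, directed = FALSE,
                                     vertices = chrs_all)
  g
}

#' Detect paralogons as pruned connected components
#'
#' Edges supported by fewer than `min_shared` families are pruned; the
#' surviving connected components are the paralogons. A component larger
#' than `max_regions` (4 for a double tetraploidization, 8 after a third
#' round) is split greedily into parts maximising intra-part edge weight
#' and annotated as a translocation: duplicated blocks scattered across
#' several present-day chromosomes still descend from one ancestral
#' region.
#'
#' @param graph weighted chromosome graph from [buildParalogonGraph()].
#' @param table a [GenomeTable-class] (used to tabulate per-family region
#'   occupancy).
#' @param species focal species.
#' @param families retained family ids.
#' @param min_shared minimum number of shared families per chromosome pair
#'   (default 2).
#' @param max_regions maximum regions per paralogon before a translocation
#'   split is applied (default 4).
#' @return list of [Paralogon-class] objects, largest first.
#' @importFrom igraph delete_edges E components V subgraph
#' @export
detectParalogons <- function(graph, table, species, families,
                             min_shared = 2L, max_regions = 4L) {
  if (igraph::vcount(graph) == 0L) return(list())
  g <- igraph::delete_edges(graph,
        igraph::E(graph)[igraph::E(graph)$weight < min_shared])
  comp <- igraph::components(g)
  out <- list()
  pid <- 0L
  for (k in seq_len(comp$no)) {
    chrs <- names(comp$membership)[comp$membership == k]
    if (length(chrs) < 2L) next
    note <- character(0L)
    parts <- list(chrs)
    if (length(chrs) > max_regions) {
      parts <- .greedySplit(g, chrs, max_regions)
      note <- sprintf(
        "component of %d chromosomes exceeds %d regions; split by intra-part weight (translocation)",
        length(chrs), max_regions)
      parts <- Filter(function(p) length(p) >= 2L, parts)
    }
    for (p in parts) {
      pid <- pid + 1L
      out[[pid]] <- .makeParalogon(pid, species, sort(p), table, families,
                                   note)
    }
  }
  out[order(-vapply(out, function(p) length(regions(p)), integer(1L)))]
}

# greedy balanced split of an oversized component: seed parts with the
# strongest edge endpoints, then attach each remaining chromosome to the
# part to which it has most total edge weight (capacity max_regions)
.greedySplit <- function(g, chrs, max_regions) {
  n_parts <- ceiling(length(chrs) / max_regions)
  w <- .weightMatrix(g, chrs)
  parts <- vector("list", n_parts)
  left <- chrs[order(-rowSums(w))]
  for (i in seq_len(n_parts)) {
    parts[[i]] <- left[1L]
    left <- left[-1L]
  }
  for (chr in left) {
    gain <- vapply(parts, function(p)
      if (length(p) >= max_regions) -Inf else sum(w[chr, p]), numeric(1L))
    parts[[which.max(gain)]] <- c(parts[[which.max(gain)]], chr)
  }
  parts
}

.weightMatrix <- function(g, chrs) {
  w <- matrix(0, length(chrs), length(chrs), dimnames = list(chrs, chrs))
  el <- igraph::as_data_frame(g, what = "edges")
  for (i in seq_len(nrow(el))) {
    a <- el$from[i]; b <- el$to[i]
    if (a %in% chrs && b %in% chrs) {
      w[a, b] <- w[a, b] + el$weight[i]
      w[b, a] <- w[a, b]
    }
  }
  w
}

.makeParalogon <- function(pid, species, chrs, table, families, note) {
  rec <- as.data.frame(table)
  rec <- rec[rec$species == species & rec$family_id %in% families, ,
             drop = FALSE]
  sup <- list()
  for (f in sort(unique(rec$family_id))) {
    occ <- sort(unique(intersect(rec$chromosome[rec$family_id == f], chrs)))
    if (length(occ) >= 2L)
      sup[[length(sup) + 1L]] <- data.frame(
        family_id = f, n_regions = length(occ),
        pattern = paste(occ, collapse = ","))
  }
  sup <- if (length(sup)) do.call(rbind, sup)
         else data.frame(family_id = character(), n_regions = integer(),
                         pattern = character())
  compl <- vapply(c("4", "3", "2"), function(k)
    sum(sup$n_regions == as.integer(k)), integer(1L))
  new("Paralogon", paralogon_id = as.integer(pid), species = species,
      regions = chrs, support = sup, completeness = compl,
      translocation_note = note)
}

#' Score a paralogon against its supporting families
#'
#' For every family touching the paralogon's regions, reports the
#' region-presence pattern, whether the family lies fully inside the
#' paralogon, and totals of full-quartet / triplet / pair families. The
#' consistency fraction is the proportion of families fully contained —
#' translocations and assembly gaps push it below 1.
#'
#' @param paralogon a [Paralogon-class].
#' @param table a [GenomeTable-class].
#' @param families family ids to score (default: the supporting families).
#' @return list with `per_family` (data.frame `family_id`, `n_inside`,
#'   `n_outside`, `consistent`), `totals` (named counts `quartet`,
#'   `triplet`, `pair`), and `consistency` (fraction in [0, 1]).
#' @export
scoreParalogon <- function(paralogon, table,
                           families = supportTable(paralogon)$family_id) {
  rec <- as.data.frame(table)
  rec <- rec[rec$species == paralogon@species &
             rec$family_id %in% families, , drop = FALSE]
  regs <- regions(paralogon)
  rows <- lapply(sort(unique(rec$family_id)), function(f) {
    chrs <- rec$chromosome[rec$family_id == f]
    data.frame(family_id = f,
               n_inside = length(unique(intersect(chrs, regs))),
               n_outside = length(unique(setdiff(chrs, regs))),
               consistent = all(chrs %in% regs))
  })
  per <- do.call(rbind, rows)
  if (is.null(per))
    per <- data.frame(family_id = character(), n_inside = integer(),
                      n_outside = integer(), consistent = logical())
  totals <- c(quartet = sum(per$n_inside == 4L),
              triplet = sum(per$n_inside == 3L),
              pair = sum(per$n_inside == 2L))
  list(per_family = per, totals = totals,
       consistency = if (nrow(per)) mean(per$consistent) else NA_real_)
}

#' Merge per-species paralogons across species
#'
#' Paralogons are detected per species and then aligned across species by
#' overlap of their supporting family sets (Jaccard index), mirroring how
#' orthologous chromosome quartets are matched between genomes.
#'
#' @param paralogon_sets named list (by species) of lists of
#'   [Paralogon-class].
#' @param min_jaccard minimum Jaccard index of supporting-family sets for
#'   two paralogons to be merged (default 0.5).
#' @return data.frame with one row per merged group: `group`, `species`,
#'   `paralogon_id`, `regions`.
#' @export
mergeParalogons <- function(paralogon_sets, min_jaccard = 0.5) {
  flat <- list()
  for (sp in names(paralogon_sets))
    for (p in paralogon_sets[[sp]])
      flat[[length(flat) + 1L]] <- list(
        species = sp, id = p@paralogon_id,
        fams = supportTable(p)$family_id,
        regions = paste(regions(p), collapse = ","))
  n <- length(flat)
  if (!n) return(data.frame(group = integer(), species = character(),
                            paralogon_id = integer(), regions = character()))
  group <- seq_len(n)
  jac <- function(a, b) {
    u <- length(union(a, b))
    if (u == 0L) 0 else length(intersect(a, b)) / u
  }
  for (i in seq_len(n - 1L)) for (j in seq(i + 1L, n)) {
    if (j > n) break
    if (flat[[i]]$species != flat[[j]]$species &&
        jac(flat[[i]]$fams, flat[[j]]$fams) >= min_jaccard)
      group[group == group[j]] <- group[i]
  }
  data.frame(group = match(group, unique(group)),
             species = vapply(flat, `[[`, character(1L), "species"),
             paralogon_id = vapply(flat, function(x) as.integer(x$id),
                                   integer(1L)),
             regions = vapply(flat, `[[`, character(1L), "regions"))
}
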