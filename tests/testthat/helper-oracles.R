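# Independent brute-force oracles for Dollo reconstruction, plus small
# builders shared across test files. These reimplement tree bookkeeping
# from scratch (recursively, on tree$edge) so they share no code with the
# package internals they check.

oracle_children <- function(tree, node) tree$edge[tree$edge[, 1] == node, 2]

oracle_tips_below <- function(tree, node) {
  ntip <- length(tree$tip.label)
  if (node <= ntip) return(tree$tip.label[node])
  unlist(lapply(oracle_children(tree, node), oracle_tips_below, tree = tree))
}

oracle_edges_below <- function(tree, node) {
  ntip <- length(tree$tip.label)
  if (node <= ntip) return(matrix(integer(), 0, 2))
  kids <- oracle_children(tree, node)
  rows <- cbind(node, kids)
  for (k in kids) rows <- rbind(rows, oracle_edges_below(tree, k))
  rows
}

# leaf presence under a single gain at `gain` and a set of loss edges
# (matrix parent,child): a leaf carries the intron iff it lies below the
# gain and below no loss edge
oracle_leaf_presence <- function(tree, gain, loss_children) {
  tips <- oracle_tips_below(tree, gain)
  for (ch in loss_children)
    tips <- setdiff(tips, oracle_tips_below(tree, ch))
  tips
}

# exhaustive minimum cost under the single-gain (Dollo) constraint:
# min over gain nodes and all subsets of edges below as losses
oracle_dollo_cost <- function(tree, pattern) {
  ntip <- length(tree$tip.label)
  all_nodes <- seq_len(ntip + tree$Nnode)
  below <- lapply(all_nodes, oracle_tips_below, tree = tree)
  informative <- names(pattern)[!is.na(pattern)]
  want <- intersect(informative, names(pattern)[pattern %in% 1L])
  best <- Inf
  for (g in all_nodes) {
    if (!all(want %in% below[[g]])) next
    edges <- oracle_edges_below(tree, g)
    ne <- nrow(edges)
    for (mask in 0:(2^ne - 1)) {
      sel <- which(bitwAnd(mask, 2^(seq_len(ne) - 1)) > 0)
      if (1 + length(sel) >= best) next
      carriers <- below[[g]]
      for (ch in edges[sel, 2]) carriers <- setdiff(carriers, below[[ch]])
      if (setequal(intersect(informative, carriers), want))
        best <- 1 + length(sel)
    }
  }
  best
}

# exhaustive minimum over arbitrary gain/loss edge labelings (multiple
# gains allowed): each edge (plus a virtual root edge) is none/gain/loss;
# a leaf's state is set by the most recent event on its root path
oracle_multi_gain_cost <- function(tree, pattern) {
  ntip <- length(tree$tip.label)
  root <- ntip + 1L
  edges <- rbind(cbind(0L, root), tree$edge)
  ne <- nrow(edges)
  informative <- names(pattern)[!is.na(pattern)]
  path_nodes <- lapply(seq_len(ntip), function(tip) {
    path <- tip
    n <- tip
    while (length(up <- tree$edge[tree$edge[, 2] == n, 1])) {
      path <- c(up, path)
      n <- up
    }
    path
  })
  best <- Inf
  lab <- rep(0L, ne)
  repeat {
    cost <- sum(lab > 0L)
    if (cost < best) {
      ok <- TRUE
      for (tip in seq_len(ntip)) {
        lbl <- tree$tip.label[tip]
        if (!lbl %in% informative) next
        state <- 0L
        nodes <- path_nodes[[tip]]
        for (n in nodes) {
          e <- which(edges[, 2] == n)
          if (length(e) && lab[e] == 1L) state <- 1L
          if (length(e) && lab[e] == 2L) state <- 0L
        }
        if (state != pattern[[lbl]]) { ok <- FALSE; break }
      }
      if (ok) best <- cost
    }
    # increment base-3 counter
    i <- 1L
    while (i <= ne) {
      lab[i] <- lab[i] + 1L
      if (lab[i] <= 2L) break
      lab[i] <- 0L
      i <- i + 1L
    }
    if (i > ne) break
  }
  best
}

# small reusable guide tree (8 leaves, labelled internals)
sim_tree8 <- function()
  ape::read.tree(
    text = "(((A,B)ab,(C,D)cd)abcd,((E,F)ef,(G,H)gh)efgh)root;")

# run projection -> clustering -> matrix on a simulated intron history
intron_pipeline <- function(sim, tree) {
  sites <- do.call(rbind, lapply(sim$models, projectIntrons,
                                 aln = sim$alignment))
  cl <- clusterIntronSites(sites)
  mat <- buildPresenceMatrix(cl, names(sim$models))
  list(clustering = cl, matrix = mat,
       events = inferGainsDollo(mat, tree))
}

# map each truth intron (by column/phase) to its inferred gain-node label
match_truth_gains <- function(pipeline, truth) {
  key <- paste(pipeline$clustering$clusters$column,
               pipeline$clustering$clusters$phase)
  cid <- pipeline$clustering$clusters$cluster_id[
    match(paste(truth$column, truth$phase), key)]
  pipeline$events$gain_node[match(as.character(cid),
                                  pipeline$events$cluster_id)]
}
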