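# --- small rooted-tree helpers on ape::phylo -------------------------------

.nodeLabel <- function(tree, node) {
  ntip <- length(tree$tip.label)
  if (node <= ntip) return(tree$tip.label[node])
  lbl <- tree$node.label
  if (!is.null(lbl) && !is.na(lbl[node - ntip]) && nzchar(lbl[node - ntip]))
    lbl[node - ntip]
  else paste0("node", node)
}

# leaves (tip numbers) below each node, node can be a tip
.cladeTips <- function(tree, node) {
  ntip <- length(tree$tip.label)
  if (node <= ntip) return(node)
  unlist(.descendantTips(tree, node))
}

# iterative descendant-tip search, handles polytomies
.descendantTips <- function(tree, node) {
  ntip <- length(tree$tip.label)
  out <- integer()
  stack <- node
  kids <- split(tree$edge[, 2L], tree$edge[, 1L])
  while (length(stack)) {
    n <- stack[[1L]]; stack <- stack[-1L]
    ch <- kids[[as.character(n)]]
    for (c in ch) {
      if (c <= ntip) out <- c(out, c) else stack <- c(stack, c)
    }
  }
  out
}

# topological depth (edges from root) for every node
.nodeDepths <- function(tree) {
  ntip <- length(tree$tip.label)
  depth <- integer(ntip + tree$Nnode)
  # cladewise order guarantees parents precede their children
  pre <- ape::reorder.phylo(tree, "cladewise")$edge
  for (i in seq_len(nrow(pre)))
    depth[pre[i, 2L]] <- depth[pre[i, 1L]] + 1L
  depth
}

.mrcaOf <- function(tree, tips) {
  if (length(tips) == 1L) return(tips)
  ape::getMRCA(tree, tips)
}

# per-node character state given a presence pattern over tips:
#   "P" subtree holds >= 1 present leaf; "A" no present, >= 1 absent;
#   "U" only unknown leaves. Pattern: named int vector over tip labels
#   (1 present / 0 absent / NA unknown); tips missing from the pattern
#   are unknown.
.subtreeStates <- function(tree, pattern) {
  ntip <- length(tree$tip.label)
  state <- character(ntip + tree$Nnode)
  v <- pattern[tree$tip.label]
  state[seq_len(ntip)] <- ifelse(is.na(v), "U", ifelse(v == 1L, "P", "A"))
  post <- ape::reorder.phylo(tree, "postorder")$edge
  for (n in unique(post[, 1L])) state[n] <- ""
  for (i in seq_len(nrow(post))) {
    p <- post[i, 1L]; c <- post[i, 2L]
    s <- state[c]
    cur <- state[p]
    state[p] <- if (s == "P" || cur == "P") "P"
                else if (s == "A" || cur == "A") "A"
                else "U"
  }
  state
}

# minimal Dollo losses inside clade(gain): edges whose child subtree is
# purely absent while the parent subtree still holds present leaves
.lossEdges <- function(tree, gain, state) {
  clade_nodes <- if (gain <= length(tree$tip.label)) gain
                 else c(gain, .internalDescendants(tree, gain),
                        .cladeTips(tree, gain))
  edge <- tree$edge
  sel <- edge[, 1L] %in% clade_nodes &
         state[edge[, 2L]] == "A" & state[edge[, 1L]] == "P"
  edge[sel, 2L]
}

.internalDescendants <- function(tree, node) {
  ntip <- length(tree$tip.label)
  out <- integer(); stack <- node
  kids <- split(tree$edge[, 2L], tree$edge[, 1L])
  while (length(stack)) {
    n <- stack[[1L]]; stack <- stack[-1L]
    for (c in kids[[as.character(n)]]) if (c > ntip) {
      out <- c(out, c); stack <- c(stack, c)
    }
  }
  out
}

# --- Dollo inference -------------------------------------------------------

#' Infer intron insertion order by Dollo parsimony
#'
#' Under Dollo parsimony an intron is gained exactly once — at the most
#' recent common ancestor of the genes that carry it — and may then be
#' lost any number of times. For every cluster of the presence matrix the
#' gain node, the minimal loss edges below it and the event cost
#' (1 gain + losses) are reconstructed on the guide tree. Unknown cells
#' are uninformative: they force neither a loss nor a presence. Events are
#' returned root-most gain first, which reads as the inferred order of
#' intron insertions.
#'
#' @param matrix presence matrix from [buildPresenceMatrix()]; row names
#'   must be a subset of the tree's leaf labels.
#' @param tree rooted guide tree ([ape::phylo]); polytomies allowed.
#' @return data.frame with one row per cluster: `cluster_id`, `gain_node`
#'   (node label), `gain_depth` (edges from root), `n_losses`,
#'   `loss_nodes` (comma-joined labels of the subtrees lost), `cost`, and
#'   `gain_leaves` (comma-joined sorted leaves of the gain clade). Clusters
#'   with no present leaf are skipped with a warning.
#' @examples
#' tree <- ape::read.tree(text = "((A,B),(C,D));")
#' m <- rbind(A = c(x = 1L), B = c(x = 1L), C = c(x = 0L), D = c(x = 0L))
#' colnames(m) <- "x"
#' inferGainsDollo(m, tree)
#' @export
inferGainsDollo <- function(matrix, tree) {
  extra <- setdiff(rownames(matrix), tree$tip.label)
  if (length(extra))
    stop("matrix row(s) not on the tree: ", paste(extra, collapse = ", "))
  depth <- .nodeDepths(tree)
  rows <- list()
  for (cl in colnames(matrix)) {
    pattern <- matrix[, cl]
    present <- rownames(matrix)[pattern %in% 1L]
    if (!length(present)) {
      warning("cluster ", cl, " has no present leaf; skipped")
      next
    }
    state <- .subtreeStates(tree, pattern)
    gain <- .mrcaOf(tree, match(present, tree$tip.label))
    losses <- .lossEdges(tree, gain, state)
    rows[[length(rows) + 1L]] <- data.frame(
      cluster_id = cl,
      gain_node = .nodeLabel(tree, gain),
      gain_depth = depth[gain],
      n_losses = length(losses),
      loss_nodes = paste(vapply(losses, .nodeLabel, character(1L),
                                tree = tree), collapse = ","),
      cost = 1L + length(losses),
      gain_leaves = paste(sort(tree$tip.label[.cladeTips(tree, gain)]),
                          collapse = ","))
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) return(out)
  out[order(out$gain_depth), , drop = FALSE]
}

#' Enumerate alternative gain/loss scenarios for one intron
#'
#' Beside the single-gain Dollo reconstruction, a presence pattern may be
#' explained by several independent gains (parallel insertion at the same
#' alignment position). This enumerates every decomposition into disjoint
#' gain clades covering the present leaves, with minimal losses inside
#' each clade, keeping scenarios whose total cost does not exceed the
#' Dollo cost plus `slack`. Equal-cost scenarios are reported side by
#' side, never auto-resolved.
#'
#' @param pattern named integer vector over tree leaves (1/0/NA).
#' @param tree rooted guide tree.
#' @param slack cost slack above the Dollo cost (default 0).
#' @return list of scenarios, each a list with `gains` (node labels),
#'   `losses` (node labels of lost subtrees), `cost`; sorted by cost, then
#'   number of gains. The single-gain Dollo scenario is always included.
#' @export
enumerateScenarios <- function(pattern, tree, slack = 0L) {
  ntip <- length(tree$tip.label)
  present <- which(pattern[tree$tip.label] %in% 1L)
  if (!length(present)) return(list())
  state <- .subtreeStates(tree, pattern)
  dollo_gain <- .mrcaOf(tree, present)
  dollo_cost <- 1L + length(.lossEdges(tree, dollo_gain, state))
  bound <- dollo_cost + slack

  all_nodes <- seq_len(ntip + tree$Nnode)
  clade <- lapply(all_nodes, function(n) .cladeTips(tree, n))
  cand <- all_nodes[vapply(clade, function(tp)
    any(tp %in% present), logical(1L))]
  loss_for <- lapply(all_nodes, function(n) .lossEdges(tree, n, state))

  scen <- list()
  add <- function(nodes) {
    tipsets <- clade[nodes]
    cov <- unlist(tipsets)
    if (anyDuplicated(cov)) return()           # overlapping clades
    if (!all(present %in% cov)) return()       # present leaf uncovered
    losses <- unlist(loss_for[nodes])
    cost <- length(nodes) + length(losses)
    if (cost > bound) return()
    scen[[length(scen) + 1L]] <<- list(
      gains = vapply(nodes, .nodeLabel, character(1L), tree = tree),
      losses = if (length(losses))
        vapply(losses, .nodeLabel, character(1L), tree = tree)
        else character(),
      cost = cost)
  }
  for (k in seq_len(min(bound, length(cand)))) {
    combos <- utils::combn(cand, k, simplify = FALSE)
    for (cb in combos) add(cb)
  }
  ord <- order(vapply(scen, `[[`, numeric(1L), "cost"),
               vapply(scen, function(s) length(s$gains), integer(1L)))
  scen[ord]
}
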