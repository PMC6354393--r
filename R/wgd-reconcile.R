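#' Classify a gene duplication as WGD-derived or local
#'
#' A pair on the same chromosome within `local_dist_bp` is a local
#' (tandem) duplication; a pair whose two genes sit on two distinct
#' regions of one detected paralogon is attributed to the whole-genome
#' duplication that created the paralogon; anything else is left
#' unresolved. When a guide tree is supplied the WGD call additionally
#' requires the pair's duplication node (their MRCA) to lie at or above
#' the given WGD horizon node, i.e. the duplication must predate the
#' lineage's tetraploidization.
#'
#' @param pair character vector of two gene ids.
#' @param paralogons list of [Paralogon-class].
#' @param table a [GenomeTable-class] locating both genes.
#' @param local_dist_bp maximum midpoint distance for a local call
#'   (default 5e6).
#' @param tree optional guide tree; `wgd_horizon` a node label of `tree`.
#' @param wgd_horizon see `tree`.
#' @param wgd_label label used for WGD calls (default `"WGD:1R/2R"`).
#' @return list with `pair`, `call` (`"local"`, `wgd_label`, or
#'   `"unresolved"`), and `evidence` (named list).
#' @export
classifyDuplication <- function(pair, paralogons, table, local_dist_bp = 5e6,
                                tree = NULL, wgd_horizon = NULL,
                                wgd_label = "WGD:1R/2R") {
  rec <- as.data.frame(table)
  loc <- lapply(pair, function(g) {
    r <- rec[rec$gene_id == g, , drop = FALSE]
    if (nrow(r) == 0L) stop("gene '", g, "' is not located in the table")
    r[1L, ]
  })
  a <- loc[[1L]]; b <- loc[[2L]]
  if (a$chromosome == b$chromosome) {
    d <- abs((a$start + a$end) / 2 - (b$start + b$end) / 2)
    if (d <= local_dist_bp)
      return(list(pair = pair, call = "local",
                  evidence = list(chromosome = a$chromosome,
                                  distance_bp = d)))
  }
  for (p in paralogons) {
    regs <- regions(p)
    if (a$chromosome %in% regs && b$chromosome %in% regs &&
        a$chromosome != b$chromosome) {
      if (!is.null(tree) && !is.null(wgd_horizon)) {
        ok <- .predatesHorizon(tree, pair, wgd_horizon)
        if (!isTRUE(ok)) next
      }
      return(list(pair = pair, call = wgd_label,
                  evidence = list(paralogon_id = p@paralogon_id,
                                  regions = c(a$chromosome, b$chromosome))))
    }
  }
  list(pair = pair, call = "unresolved", evidence = list())
}

# TRUE when MRCA(pair) is the horizon node or one of its ancestors
.predatesHorizon <- function(tree, pair, horizon) {
  tips <- match(pair, tree$tip.label)
  if (anyNA(tips)) return(NA)
  mrca <- .mrcaOf(tree, tips)
  ntip <- length(tree$tip.label)
  hz <- if (horizon %in% tree$tip.label) match(horizon, tree$tip.label)
        else ntip + match(horizon, tree$node.label)
  if (is.na(hz)) return(NA)
  anc <- hz
  repeat {
    if (anc == mrca) return(TRUE)
    up <- tree$edge[tree$edge[, 2L] == anc, 1L]
    if (!length(up)) return(FALSE)
    anc <- up
  }
}

#' Count the pre-WGD ancestral genes
#'
#' The number of distinct ohnolog groups, i.e. of genes present in the
#' lineage before the first tetraploidization. A gene assigned to two
#' groups is an error.
#'
#' @param groups data.frame with columns `group_id`, `gene_id`.
#' @return integer.
#' @examples
#' g <- data.frame(group_id = c("x", "x", "y"), gene_id = c("a", "b", "c"))
#' ancestralCount(g)  # 2
#' @export
ancestralCount <- function(groups) {
  dup <- unique(groups$gene_id[duplicated(groups$gene_id)])
  if (length(dup))
    stop("gene(s) assigned to more than one group: ",
         paste(dup, collapse = ", "))
  length(unique(groups$group_id))
}

#' Post-WGD retention profile of ohnolog groups
#'
#' Histogram of how many ohnologs each ancestral gene retained after the
#' tetraploidizations (4 = full quartet, down to 1 = single survivor).
#' The histogram sums to the ancestral count and its weighted sum to the
#' total gene count.
#'
#' @param groups data.frame with columns `group_id`, `gene_id`.
#' @return named integer vector over retained counts `"4".."1"` (only
#'   nonzero classes present, descending).
#' @export
retentionProfile <- function(groups) {
  ancestralCount(groups)  # validates single assignment
  sizes <- table(groups$group_id)
  h <- table(factor(as.integer(sizes)))
  out <- as.integer(h)
  names(out) <- names(h)
  out[order(-as.integer(names(out)))]
}

#' Upper bound on ohnolog losses
#'
#' After `rounds` tetraploidizations every ancestral gene would have
#' 2^rounds copies; the difference from the retained total is the maximum
#' number of duplicate losses. It is an upper bound: a duplicate lost
#' already after the first round removes two potential descendants, so
#' the true number of loss events can be smaller.
#'
#' @param groups data.frame with columns `group_id`, `gene_id`.
#' @param rounds number of tetraploidizations (default 2).
#' @return integer upper bound.
#' @export
maxLosses <- function(groups, rounds = 2L) {
  stopifnot(rounds >= 1L)
  as.integer(ancestralCount(groups) * 2^rounds - length(unique(groups$gene_id)))
}

#' Derive a descendant repertoire by applying losses and gains
#'
#' @param base parent [Repertoire-class].
#' @param label label of the descendant node.
#' @param losses genes lost along the edge (must all be in `base`).
#' @param gains genes gained (e.g. local duplicates; must be new).
#' @param unconfirmed subset of `losses` that are "not identified" rather
#'   than demonstrably lost (assembly caveat); counted as losses but
#'   flagged in the ledger.
#' @return a new [Repertoire-class]; the identity
#'   `count = parent - losses + gains` always holds.
#' @examples
#' v <- repertoire("post2R", paste0("g", 1:19))
#' h <- lineageRepertoire(v, "human", losses = c("g1", "g2", "g3"))
#' repertoireCount(h)  # 16
#' @export
lineageRepertoire <- function(base, label, losses = character(),
                              gains = character(),
                              unconfirmed = character()) {
  genes <- repertoireGenes(base)
  bad <- setdiff(losses, genes)
  if (length(bad))
    stop("loss of gene(s) absent from '", base@label, "': ",
         paste(bad, collapse = ", "))
  clash <- intersect(gains, setdiff(genes, losses))
  if (length(clash))
    stop("gain of gene(s) already present: ", paste(clash, collapse = ", "))
  ledger <- rbind(
    eventLedger(base),
    if (length(losses)) data.frame(event = "loss", gene = losses,
                                   unconfirmed = losses %in% unconfirmed),
    if (length(gains)) data.frame(event = "gain", gene = gains,
                                  unconfirmed = FALSE))
  out <- repertoire(label, c(setdiff(genes, losses), gains), ledger)
  stopifnot(repertoireCount(out) ==
              repertoireCount(base) - length(losses) + length(gains))
  out
}

#' Apply a whole-genome duplication to a repertoire
#'
#' Every gene of `retained_duplicates` gains a co-ohnolog named with
#' `suffix` (the ".2"-style naming used for teleost 3R duplicates);
#' duplicates of the remaining genes are taken as immediately lost, so
#' the count grows by exactly the number of retained duplicates.
#'
#' @param base parent [Repertoire-class].
#' @param label label of the post-WGD node.
#' @param retained_duplicates genes whose extra WGD copy survives (subset
#'   of the base gene list).
#' @param suffix name suffix for the new copies (default `".2"`).
#' @return a new [Repertoire-class].
#' @examples
#' pre <- repertoire("pre3R", paste0("g", 1:20))
#' post <- applyWGD(pre, "post3R", paste0("g", 1:11))
#' repertoireCount(post)  # 31
#' @export
applyWGD <- function(base, label, retained_duplicates, suffix = ".2") {
  genes <- repertoireGenes(base)
  bad <- setdiff(retained_duplicates, genes)
  if (length(bad))
    stop("cannot retain duplicate of absent gene(s): ",
         paste(bad, collapse = ", "))
  dups <- if (length(retained_duplicates))
    paste0(retained_duplicates, suffix) else character(0)
  ledger <- rbind(eventLedger(base),
                  if (length(dups))
                    data.frame(event = "wgd_duplicate", gene = dups,
                               unconfirmed = FALSE))
  out <- repertoire(label, c(genes, dups), ledger)
  stopifnot(repertoireCount(out) ==
              repertoireCount(base) + length(retained_duplicates))
  out
}

#' Check the ledger identity along a repertoire chain
#'
#' Asserts count conservation: final count = root count + gains +
#' WGD duplicates - losses, using the accumulated ledger.
#'
#' @param root the ancestral [Repertoire-class].
#' @param final a descendant [Repertoire-class] derived from it.
#' @return TRUE (invisibly) or an error.
#' @export
checkLedgerIdentity <- function(root, final) {
  led <- eventLedger(final)
  gains <- sum(led$event %in% c("gain", "wgd_duplicate"))
  losses <- sum(led$event == "loss")
  if (repertoireCount(final) !=
      repertoireCount(root) + gains - losses)
    stop("ledger identity violated for '", final@label, "'")
  invisible(TRUE)
}
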