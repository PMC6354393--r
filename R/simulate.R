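#' Build a simulation configuration
#'
#' Parameters of the forward genome-evolution simulator. Defaults describe
#' a desk-scale genome that still behaves like the biological setting: a
#' handful of chromosomes carrying one gene per family at 1 Mb spacing (so
#' a 10 Mb neighbour window holds about 21 genes), one to three rounds of
#' tetraploidization, independent per-duplicate loss, occasional tandem
#' duplication and translocation.
#'
#' @param seed integer seed; the single source of randomness.
#' @param n_families number of gene families (default 50).
#' @param n_chromosomes ancestral chromosomes (default 5).
#' @param genes_per_chromosome capacity per ancestral chromosome
#'   (default 10; `n_families` must fit).
#' @param wgd_schedule ordered character vector of tetraploidizations,
#'   e.g. `c("1R", "2R")` (default); each doubles every chromosome.
#' @param loss_prob per-duplicate loss probability after each WGD
#'   (default 0.2).
#' @param local_dup_rate per-gene tandem-duplication probability
#'   (default 0).
#' @param transloc_rate per-gene translocation probability (default 0).
#' @param gene_spacing bp between gene starts (default 1e6).
#' @param gene_length bp of each gene (default 2e4).
#' @param protein_length residues of the simulated ancestral protein
#'   (intron simulator; default 300).
#' @param intron_count introns to gain over the tree (default 10).
#' @param intron_gain_rate reserved: gains are placed uniformly on edges,
#'   one per intron (Dollo by construction).
#' @param intron_loss_rate per-edge loss probability below a gain
#'   (default 0).
#' @param homoplasy inject a second, independent gain for each intron with
#'   this probability (default 0 = Dollo histories only).
#' @return a validated list of class `simulation_config`.
#' @export
simulationConfig <- function(seed, n_families = 50L, n_chromosomes = 5L,
                             genes_per_chromosome = 10L,
                             wgd_schedule = c("1R", "2R"),
                             loss_prob = 0.2, local_dup_rate = 0,
                             transloc_rate = 0, gene_spacing = 1e6,
                             gene_length = 2e4, protein_length = 300L,
                             intron_count = 10L, intron_gain_rate = 1,
                             intron_loss_rate = 0, homoplasy = 0) {
  probs <- c(loss_prob, local_dup_rate, transloc_rate, intron_loss_rate,
             homoplasy)
  if (any(probs < 0 | probs > 1))
    stop("all probabilities must lie in [0, 1]")
  if (n_chromosomes < 1L) stop("at least one chromosome is required")
  if (n_families > n_chromosomes * genes_per_chromosome)
    stop("n_families exceeds chromosome capacity")
  structure(list(seed = as.integer(seed), n_families = n_families,
                 n_chromosomes = n_chromosomes,
                 genes_per_chromosome = genes_per_chromosome,
                 wgd_schedule = wgd_schedule, loss_prob = loss_prob,
                 local_dup_rate = local_dup_rate,
                 transloc_rate = transloc_rate,
                 gene_spacing = gene_spacing, gene_length = gene_length,
                 protein_length = protein_length,
                 intron_count = intron_count,
                 intron_gain_rate = intron_gain_rate,
                 intron_loss_rate = intron_loss_rate,
                 homoplasy = homoplasy),
            class = "simulation_config")
}

#' Forward-simulate genome evolution through tetraploidizations
#'
#' Starts from an ancestral genome with one gene per family laid out on
#' `n_chromosomes` chromosomes, then applies each scheduled WGD: every
#' chromosome is doubled (labels gain `a`/`b` suffixes) and every
#' duplicated gene copy is independently lost with `loss_prob`. Tandem
#' duplications insert a copy next to the parent; translocations move a
#' gene to a random other chromosome. The focal species carries the WGDs;
#' an outgroup species diverges before them. Truth records every ohnolog
#' group, the daughter-chromosome sets of each ancestral chromosome, the
#' per-pair duplication mechanism, and every loss/translocation.
#'
#' @param config a [simulationConfig()].
#' @return list with `table` ([GenomeTable-class]: focal + outgroup),
#'   `truth` (list: `ohnolog_groups`, `chromosome_sets`, `pair_calls`,
#'   `events`), `species_tree` (Newick string), `config`.
#' @examples
#' sim <- simulateGenomeEvolution(simulationConfig(seed = 1, loss_prob = 0))
#' table(table(as.data.frame(sim$table)$family_id))  # all quartets + outgroup
#' @importFrom withr with_seed
#' @export
simulateGenomeEvolution <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  withr::with_seed(config$seed, .simulateGenome(config))
}

.simulateGenome <- function(cf) {
  fam <- sprintf("fam%03d", seq_len(cf$n_families))
  chr0 <- sprintf("chr%d", seq_len(cf$n_chromosomes))
  # ancestral layout: fill chromosomes family by family
  genes <- data.frame(
    gene_id = paste0(fam, ".0"), family_id = fam,
    chromosome = rep(chr0, each = cf$genes_per_chromosome)[
      seq_len(cf$n_families)],
    stringsAsFactors = FALSE)
  events <- list()
  anc_of_chr <- stats::setNames(chr0, chr0)

  for (ev in cf$wgd_schedule) {
    a <- genes; b <- genes
    a$chromosome <- paste0(genes$chromosome, "a")
    b$chromosome <- paste0(genes$chromosome, "b")
    a$gene_id <- paste0(genes$gene_id, "a")
    b$gene_id <- paste0(genes$gene_id, "b")
    new_anc <- c(stats::setNames(anc_of_chr[genes$chromosome], a$chromosome),
                 stats::setNames(anc_of_chr[genes$chromosome], b$chromosome))
    anc_of_chr <- c(anc_of_chr, new_anc[!duplicated(names(new_anc))])
    genes <- rbind(a, b)
  }
  # fractionation: every final duplicate is lost independently; drawing
  # all losses after the last round keeps the loss-count bound tight
  if (length(cf$wgd_schedule)) {
    lost <- stats::runif(nrow(genes)) < cf$loss_prob
    if (any(lost))
      events[[length(events) + 1L]] <- data.frame(
        event = "ohnolog_loss",
        wgd = cf$wgd_schedule[length(cf$wgd_schedule)],
        gene_id = genes$gene_id[lost])
    genes <- genes[!lost, , drop = FALSE]
  }

  # tandem duplications: copy inserted next to its parent
  td <- stats::runif(nrow(genes)) < cf$local_dup_rate
  if (any(td)) {
    copies <- genes[td, , drop = FALSE]
    copies$gene_id <- paste0(copies$gene_id, ".t")
    events[[length(events) + 1L]] <- data.frame(
      event = "tandem_duplication", wgd = NA, gene_id = copies$gene_id)
    genes <- rbind(genes, copies)
  }

  # translocations: move to a uniformly chosen other chromosome
  chrs <- sort(unique(genes$chromosome))
  tr <- stats::runif(nrow(genes)) < cf$transloc_rate & length(chrs) > 1L
  if (any(tr)) {
    for (i in which(tr)) {
      others <- setdiff(chrs, genes$chromosome[i])
      genes$chromosome[i] <- sample(others, 1L)
    }
    events[[length(events) + 1L]] <- data.frame(
      event = "translocation", wgd = NA, gene_id = genes$gene_id[tr])
  }

  # coordinates: order within chromosome, tandem copies next to parents
  genes$base <- sub("\\.t$", "", genes$gene_id)
  genes <- genes[order(genes$chromosome, genes$base, genes$gene_id), ]
  pos <- unlist(lapply(split(seq_len(nrow(genes)), genes$chromosome),
                       seq_along), use.names = FALSE)
  genes$start <- as.integer((pos - 1L) * cf$gene_spacing + 1L)
  genes$end <- as.integer(genes$start + cf$gene_length - 1L)
  genes$strand <- "+"
  genes$species <- "focal"

  outgroup <- data.frame(
    species = "outgroup", gene_id = paste0("out_", fam),
    family_id = fam, chromosome = rep(chr0, each = cf$genes_per_chromosome)[
      seq_len(cf$n_families)],
    start = as.integer(((seq_len(cf$n_families) - 1L) %%
                          cf$genes_per_chromosome) * cf$gene_spacing + 1L),
    stringsAsFactors = FALSE)
  outgroup$end <- as.integer(outgroup$start + cf$gene_length - 1L)
  outgroup$strand <- "+"

  tab <- genomeTable(rbind(
    genes[, c("species", "gene_id", "family_id", "chromosome", "start",
              "end", "strand")],
    outgroup[, c("species", "gene_id", "family_id", "chromosome", "start",
                 "end", "strand")]))

  truth <- list(
    ohnolog_groups = split(genes$gene_id, genes$family_id),
    chromosome_sets = lapply(stats::setNames(chr0, chr0), function(c0)
      sort(unique(genes$chromosome[
        anc_of_chr[genes$chromosome] == c0]))),
    pair_calls = .truePairCalls(genes),
    events = if (length(events)) do.call(rbind, events)
             else data.frame(event = character(), wgd = character(),
                             gene_id = character()))
  list(table = tab, truth = truth,
       species_tree = "(outgroup,focal);", config = cf)
}

# duplication mechanism for every within-family gene pair: tandem copies
# are local; otherwise the pair descends from a WGD
.truePairCalls <- function(genes) {
  out <- list()
  for (f in unique(genes$family_id)) {
    ids <- genes$gene_id[genes$family_id == f]
    if (length(ids) < 2L) next
    cb <- utils::combn(sort(ids), 2L)
    for (k in seq_len(ncol(cb))) {
      a <- cb[1L, k]; b <- cb[2L, k]
      call <- if (sub("\\.t$", "", a) == sub("\\.t$", "", b) ||
                  grepl("\\.t$", a) && sub("\\.t$", "", a) == b ||
                  grepl("\\.t$", b) && sub("\\.t$", "", b) == a)
        "local" else "WGD"
      out[[length(out) + 1L]] <- data.frame(gene_a = a, gene_b = b,
                                            call = call, family_id = f)
    }
  }
  if (length(out)) do.call(rbind, out)
  else data.frame(gene_a = character(), gene_b = character(),
                  call = character(), family_id = character())
}

#' Simulate an intron gain/loss history on a guide tree
#'
#' An ancestral intron-less protein-coding gene evolves along the tree:
#' each intron is gained exactly once on a uniformly chosen edge (Dollo by
#' construction) and subsequently lost on each edge below the gain with
#' `intron_loss_rate`; with probability `homoplasy` an intron receives a
#' second independent gain on a disjoint edge. Leaf gene models (CDS split
#' at the surviving intron positions) and the trivially gap-free protein
#' alignment are emitted together with the full truth record.
#'
#' @param tree rooted [ape::phylo] guide tree with >= 2 leaves.
#' @param config a [simulationConfig()].
#' @return list with `models` (named list of [GeneModel-class] per leaf),
#'   `alignment` ([ProteinAlignment-class]), `truth` (data.frame per
#'   intron: `intron`, `column`, `phase`, `gain_node`, `gain2_node`,
#'   `observable_node` = MRCA of surviving carriers, `loss_nodes`,
#'   `carriers`), `tree`.
#' @export
simulateIntronHistory <- function(tree, config) {
  stopifnot(inherits(config, "simulation_config"),
            length(tree$tip.label) >= 2L)
  withr::with_seed(config$seed + 1L, .simulateIntrons(tree, config))
}

.simulateIntrons <- function(tree, cf) {
  ntip <- length(tree$tip.label)
  root <- ntip + 1L
  edges <- rbind(cbind(0L, root), tree$edge)   # virtual root edge first
  L <- cf$protein_length
  # distinct residue boundaries, >= 2 codons apart so clustering is exact
  slots <- seq(2L, L - 2L, by = 2L)
  cols <- sort(sample(slots, cf$intron_count))
  phase <- sample(0:2, cf$intron_count, replace = TRUE)

  presence <- matrix(0L, ntip, cf$intron_count,
                     dimnames = list(tree$tip.label, NULL))
  rec <- list()
  for (i in seq_len(cf$intron_count)) {
    gi <- sample(nrow(edges), 1L)
    gain_node <- edges[gi, 2L]
    below <- .edgesBelow(tree, gain_node)
    lost_edges <- below[stats::runif(nrow(below)) < cf$intron_loss_rate, ,
                        drop = FALSE]
    carriers <- .carriersOf(tree, gain_node, lost_edges)
    gain2 <- NA_integer_
    if (stats::runif(1L) < cf$homoplasy) {
      outside <- setdiff(seq_len(ntip + tree$Nnode),
                         c(.cladeTips(tree, gain_node),
                           if (gain_node > ntip)
                             c(gain_node,
                               .internalDescendants(tree, gain_node))))
      outside <- setdiff(outside, .ancestorsOf(tree, gain_node))
      if (length(outside)) {
        gain2 <- outside[sample(length(outside), 1L)]
        carriers <- union(carriers, .cladeTips(tree, gain2))
      }
    }
    presence[carriers, i] <- 1L
    obs <- if (length(carriers)) .mrcaOf(tree, carriers) else NA_integer_
    rec[[i]] <- data.frame(
      intron = i, column = cols[i], phase = phase[i],
      gain_node = .nodeLabel(tree, gain_node),
      gain2_node = if (is.na(gain2)) NA_character_
                   else .nodeLabel(tree, gain2),
      observable_node = if (is.na(obs)) NA_character_
                        else .nodeLabel(tree, obs),
      loss_nodes = paste(vapply(lost_edges[, 2L], .nodeLabel,
                                character(1L), tree = tree),
                         collapse = ","),
      carriers = paste(sort(tree$tip.label[carriers]), collapse = ","))
  }
  truth <- do.call(rbind, rec)

  prot <- .fixtureProtein(L)
  models <- lapply(tree$tip.label, function(leaf) {
    idx <- which(presence[leaf, ] == 1L)
    nts <- sort(3L * cols[idx] + phase[idx])
    bounds <- c(0L, nts, 3L * (L + 1L))
    lens <- diff(bounds)
    starts <- 1000L + cumsum(c(0L, utils::head(lens, -1L) + 200L))
    geneModel(leaf, species = "sim", chromosome = paste0("chr_", leaf),
              strand = "+", cds = cbind(start = starts,
                                        end = starts + lens))
  })
  names(models) <- tree$tip.label
  aln <- new("ProteinAlignment", Biostrings::AAStringSet(
    stats::setNames(rep(prot, ntip), tree$tip.label)))
  list(models = models, alignment = aln, truth = truth, tree = tree)
}

# edges strictly below a node (matrix parent, child)
.edgesBelow <- function(tree, node) {
  ntip <- length(tree$tip.label)
  if (node <= ntip)
    return(matrix(integer(), 0L, 2L))
  nodes <- c(node, .internalDescendants(tree, node))
  tree$edge[tree$edge[, 1L] %in% nodes, , drop = FALSE]
}

.ancestorsOf <- function(tree, node) {
  out <- integer()
  repeat {
    up <- tree$edge[tree$edge[, 2L] == node, 1L]
    if (!length(up)) return(out)
    out <- c(out, up)
    node <- up
  }
}

# leaves carrying the intron: below the gain, not below any loss edge
.carriersOf <- function(tree, gain_node, lost_edges) {
  tips <- .cladeTips(tree, gain_node)
  if (nrow(lost_edges))
    for (k in seq_len(nrow(lost_edges)))
      tips <- setdiff(tips, .cladeTips(tree, lost_edges[k, 2L]))
  tips
}
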