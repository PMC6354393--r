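#' @importFrom stats setNames aggregate na.omit runif
#' @importFrom utils head combn
NULL

.writeManifest <- function(outdir, stage, inputs, params, seed = NULL) {
  manifest <- list(
    stage = stage,
    inputs = inputs,
    parameters = params,
    seed = seed,
    r_version = as.character(getRversion()),
    package_version = as.character(utils::packageVersion("paralogon")),
    timestamp = format(Sys.time(), tz = "UTC"))
  jsonlite::write_json(manifest, file.path(outdir, "run_manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, null = "null")
}

#' Run the intron-atlas stage
#'
#' Reads gene models, alignment and guide tree, projects and clusters the
#' introns, reconstructs insertion order by Dollo parsimony, and writes
#' the presence matrix, event table and near-miss report as TSV, plus a
#' machine-readable run manifest.
#'
#' @param gff3,alignment,tree input file paths.
#' @param outdir output directory (created).
#' @param shift_tolerance codon shift reported as a near miss (default 1).
#' @param partial_genes genes whose absences should be recorded as unknown.
#' @return invisible list with `matrix`, `events`, `near_misses`,
#'   `clusters` and the output paths.
#' @export
runIntrons <- function(gff3, alignment, tree, outdir,
                       shift_tolerance = 1L, partial_genes = character()) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  models <- readGeneModels(gff3)
  aln <- readProteinAlignment(alignment)
  gtree <- readGuideTree(tree)
  sites <- do.call(rbind, lapply(models, projectIntrons, aln = aln))
  if (is.null(sites))
    sites <- data.frame(gene_id = character(), protein_id = character(),
                        residue_index = integer(), phase = integer(),
                        column = integer())
  clustering <- clusterIntronSites(sites, shift_tolerance = shift_tolerance)
  mat <- buildPresenceMatrix(clustering, names(models),
                             partial_genes = partial_genes,
                             alignment = aln)
  events <- inferGainsDollo(mat[rownames(mat) %in% gtree$tip.label, ,
                                drop = FALSE], gtree)
  if (is.null(events))
    events <- data.frame(cluster_id = character(), gain_node = character(),
                         gain_depth = integer(), n_losses = integer(),
                         loss_nodes = character(), cost = integer(),
                         gain_leaves = character())
  paths <- list(matrix = file.path(outdir, "presence_matrix.tsv"),
                events = file.path(outdir, "insertion_events.tsv"),
                near = file.path(outdir, "near_misses.tsv"))
  m <- mat; m[is.na(m)] <- "?"
  utils::write.table(cbind(gene_id = rownames(m), as.data.frame(m)),
                     paths$matrix, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(events, paths$events, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(clustering$near_misses, paths$near, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  .writeManifest(outdir, "introns",
                 list(gff3 = gff3, alignment = alignment, tree = tree),
                 list(shift_tolerance = shift_tolerance))
  invisible(list(matrix = mat, events = events,
                 near_misses = clustering$near_misses,
                 clusters = clustering$clusters, paths = paths))
}

#' Run the paralogon-detection stage
#'
#' @param genome_table path to a genome table TSV.
#' @param species focal species.
#' @param outdir output directory.
#' @param curation optional path to a curation-flag TSV; when missing all
#'   families are retained with a warning.
#' @param min_shared minimum shared families per chromosome pair.
#' @param max_regions regions per paralogon before a translocation split.
#' @param min_members minimum family size.
#' @return invisible list with `paralogons`, `filter`, `scores`, paths.
#' @export
runParalogons <- function(genome_table, species, outdir, curation = NULL,
                          min_shared = 2L, max_regions = 4L,
                          min_members = 2L) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  tab <- readGenomeTable(genome_table)
  flags <- if (!is.null(curation)) readCurationFlags(curation) else NULL
  filt <- filterFamilies(tab, species, flags, min_members = min_members)
  graph <- buildParalogonGraph(tab, species, filt$retained)
  pls <- detectParalogons(graph, tab, species, filt$retained,
                          min_shared = min_shared,
                          max_regions = max_regions)
  scores <- lapply(pls, scoreParalogon, table = tab)
  report <- do.call(rbind, lapply(seq_along(pls), function(i) {
    p <- pls[[i]]
    data.frame(paralogon_id = p@paralogon_id, species = p@species,
               regions = paste(regions(p), collapse = ","),
               n_regions = length(regions(p)),
               families_4 = completeness(p)[["4"]],
               families_3 = completeness(p)[["3"]],
               families_2 = completeness(p)[["2"]],
               consistency = scores[[i]]$consistency,
               translocation = length(p@translocation_note) > 0L)
  }))
  path <- file.path(outdir, "paralogons.tsv")
  if (is.null(report))
    report <- data.frame(paralogon_id = integer(), species = character(),
                         regions = character(), n_regions = integer(),
                         families_4 = integer(), families_3 = integer(),
                         families_2 = integer(), consistency = numeric(),
                         translocation = logical())
  utils::write.table(report, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  jsonlite::write_json(report, file.path(outdir, "paralogons.json"),
                       dataframe = "rows", auto_unbox = TRUE)
  .writeManifest(outdir, "paralogons",
                 list(genome_table = genome_table, curation = curation),
                 list(species = species, min_shared = min_shared,
                      max_regions = max_regions, min_members = min_members))
  invisible(list(paralogons = pls, filter = filt, scores = scores,
                 report = report, path = path))
}

#' Run the repertoire-reconciliation stage
#'
#' Reads an ohnolog-group table and a lineage event ledger, reconstructs
#' the per-lineage repertoires by replaying losses and gains from the
#' post-WGD ancestral repertoire, and writes one repertoire table per
#' lineage plus a summary.
#'
#' @param ohnolog_tsv path to a TSV with columns `group_id`, `gene_id`.
#' @param ledger_tsv path to a TSV with columns `lineage`, `event`,
#'   `gene` and optional `unconfirmed`.
#' @param outdir output directory.
#' @param base_label label for the ancestral repertoire.
#' @return invisible list with `base` repertoire, `lineages` (named list
#'   of [Repertoire-class]), `summary` data.frame, `groups`.
#' @export
runReconcile <- function(ohnolog_tsv, ledger_tsv, outdir,
                         base_label = "post_WGD_ancestor") {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  groups <- utils::read.delim(ohnolog_tsv, stringsAsFactors = FALSE)
  led <- utils::read.delim(ledger_tsv, stringsAsFactors = FALSE)
  if (is.null(led$unconfirmed)) led$unconfirmed <- FALSE
  names(led) <- sub("^gene$", "gene", names(led))
  base <- repertoire(base_label, unique(groups$gene_id))
  lineages <- list()
  for (ln in unique(led$lineage)) {
    e <- led[led$lineage == ln, , drop = FALSE]
    lineages[[ln]] <- lineageRepertoire(
      base, ln,
      losses = e$gene[e$event == "loss"],
      gains = e$gene[e$event == "gain"],
      unconfirmed = e$gene[e$event == "loss" & as.logical(e$unconfirmed)])
    checkLedgerIdentity(base, lineages[[ln]])
  }
  summary <- data.frame(
    lineage = c(base_label, names(lineages)),
    n_genes = c(repertoireCount(base),
                vapply(lineages, repertoireCount, integer(1L))))
  utils::write.table(summary, file.path(outdir, "repertoire_summary.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  for (ln in names(lineages))
    utils::write.table(
      data.frame(lineage = ln, gene = repertoireGenes(lineages[[ln]])),
      file.path(outdir, paste0("repertoire_", ln, ".tsv")),
      sep = "\t", quote = FALSE, row.names = FALSE)
  scen <- data.frame(
    ancestral_genes = ancestralCount(groups),
    post_wgd_genes = length(unique(groups$gene_id)),
    max_losses = maxLosses(groups))
  utils::write.table(scen, file.path(outdir, "scenario_report.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  .writeManifest(outdir, "reconcile",
                 list(ohnolog = ohnolog_tsv, ledger = ledger_tsv),
                 list(base_label = base_label))
  invisible(list(base = base, lineages = lineages, summary = summary,
                 groups = groups))
}

#' Run the simulator stage
#'
#' @param seed integer seed (mandatory; sole source of randomness).
#' @param outdir output directory.
#' @param ... further arguments to [simulationConfig()].
#' @return invisible list with the simulation result and file paths.
#' @export
runSimulate <- function(seed, outdir, ...) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  cf <- simulationConfig(seed = seed, ...)
  sim <- simulateGenomeEvolution(cf)
  writeGenomeTable(sim$table, file.path(outdir, "genome_table.tsv"))
  writeLines(sim$species_tree, file.path(outdir, "species_tree.nwk"))
  truth_df <- data.frame(
    family_id = rep(names(sim$truth$ohnolog_groups),
                    lengths(sim$truth$ohnolog_groups)),
    gene_id = unlist(sim$truth$ohnolog_groups, use.names = FALSE))
  utils::write.table(truth_df, file.path(outdir, "truth_ohnologs.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(sim$truth$pair_calls,
                     file.path(outdir, "truth_pairs.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  .writeManifest(outdir, "simulate", list(),
                 cf[setdiff(names(cf), "wgd_schedule")], seed = seed)
  invisible(list(sim = sim, outdir = outdir))
}

#' Emit the packaged nAChR fixture
#'
#' @param outdir output directory.
#' @return invisible named list of paths (see [writeFixture()]).
#' @export
runFixture <- function(outdir) {
  paths <- writeFixture(outdir)
  .writeManifest(outdir, "fixture", list(), list())
  invisible(paths)
}
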