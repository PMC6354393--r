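# in-code genome builder: families laid out over chromosomes of one species
toy_table <- function(rows) {
  df <- do.call(rbind, lapply(rows, function(r)
    data.frame(species = r[[1]], gene_id = r[[2]], family_id = r[[3]],
               chromosome = r[[4]], start = as.integer(r[[5]]),
               end = as.integer(r[[5]]) + 1000L, strand = "+")))
  genomeTable(df)
}

test_that("neighbour windows use closed midpoint intervals", {
  tab <- toy_table(list(
    list("sp", "anchor", "fA", "chr1", 5e6),
    list("sp", "edge",   "fB", "chr1", 15e6),      # exactly at the boundary
    list("sp", "beyond", "fC", "chr1", 15e6 + 2000),
    list("sp", "other",  "fD", "chr2", 5e6)))
  w <- extractNeighbors(tab, "anchor", window_bp = 1e7)
  expect_setequal(w$members$gene_id, c("anchor", "edge"))
  # an anchor alone on its chromosome returns just itself
  w2 <- extractNeighbors(tab, "other")
  expect_identical(w2$members$gene_id, "other")
  expect_error(extractNeighbors(tab, "missing"), "missing")
})

test_that("simulated windows agree with a linear scan", {
  sim <- simulateGenomeEvolution(simulationConfig(seed = 4, loss_prob = 0.2))
  rec <- as.data.frame(sim$table)
  foc <- rec[rec$species == "focal", ]
  anchors <- withr::with_seed(1, sample(foc$gene_id, 5))
  for (a in anchors) {
    w <- extractNeighbors(sim$table, a, window_bp = 1e7)
    hit <- foc[foc$gene_id == a, ]
    mids <- (foc$start + foc$end) / 2
    expected <- foc$gene_id[foc$chromosome == hit$chromosome &
      abs(mids - (hit$start + hit$end) / 2) <= 1e7]
    expect_setequal(w$members$gene_id, expected)
  }
})

test_that("family filtering applies size and curation criteria", {
  tab <- toy_table(list(
    list("sp", "g1", "single", "chr1", 1e6),
    list("sp", "g2", "good", "chr1", 2e6),
    list("sp", "g3", "good", "chr2", 3e6),
    list("sp", "g4", "messy", "chr1", 4e6),
    list("sp", "g5", "messy", "chr2", 5e6),
    list("sp", "g6", "conserved", "chr1", 6e6),
    list("sp", "g7", "conserved", "chr2", 7e6)))
  flags <- data.frame(
    family_id = c("single", "good", "messy", "conserved"),
    clear_topology = c(TRUE, TRUE, FALSE, TRUE),
    strong_support = TRUE, has_outgroup = TRUE,
    low_conservation = c(FALSE, FALSE, FALSE, TRUE))
  filt <- filterFamilies(tab, "sp", flags)
  expect_identical(filt$retained, "good")
  expect_identical(
    filt$excluded$reason[match(c("single", "messy", "conserved"),
                               filt$excluded$family_id)],
    c("min_members", "topology", "conservation"))
  expect_warning(filterFamilies(tab, "sp", NULL), "retaining all")
})

test_that("co-occurrence graph counts families per chromosome pair", {
  tab <- toy_table(list(
    list("sp", "g1", "f1", "a", 1e6), list("sp", "g2", "f1", "b", 1e6),
    list("sp", "g3", "f2", "a", 2e6), list("sp", "g4", "f2", "b", 2e6),
    list("sp", "g5", "f3", "a", 3e6), list("sp", "g6", "f3", "c", 3e6)))
  g <- buildParalogonGraph(tab, "sp", c("f1", "f2", "f3"))
  el <- igraph::as_data_frame(g)
  ab <- el$weight[(el$from == "a" & el$to == "b") |
                  (el$from == "b" & el$to == "a")]
  expect_identical(as.integer(ab), 2L)
  expect_false(any(el$from == el$to))
})

test_that("paralogon detection prunes, components, and splits", {
  tab <- toy_table(c(
    lapply(1:4, function(i) list("sp", paste0("p", i), paste0("fp", i %/% 3 + 1),
                                 c("a", "b")[i %% 2 + 1], i * 1e6)),
    lapply(1:4, function(i) list("sp", paste0("q", i), paste0("fq", i %/% 3 + 1),
                                 c("c", "d")[i %% 2 + 1], i * 1e6))))
  fams <- c("fp1", "fp2", "fq1", "fq2")
  g <- buildParalogonGraph(tab, "sp", fams)
  pls <- detectParalogons(g, tab, "sp", fams, min_shared = 2L)
  expect_identical(length(pls), 2L)   # two disjoint pairs
  expect_setequal(unlist(lapply(pls, regions)), c("a", "b", "c", "d"))
  # raising min_shared above every weight empties the report
  expect_identical(length(detectParalogons(g, tab, "sp", fams,
                                           min_shared = 3L)), 0L)
})

test_that("a clean quartet yields one paralogon with full support", {
  rows <- list()
  for (f in paste0("fam", 1:4))
    for (chr in c("c1", "c2", "c3", "c4"))
      rows[[length(rows) + 1L]] <- list("sp", paste0(f, "_", chr), f, chr,
                                        1e6 * length(rows))
  tab <- toy_table(rows)
  g <- buildParalogonGraph(tab, "sp", paste0("fam", 1:4))
  pls <- detectParalogons(g, tab, "sp", paste0("fam", 1:4))
  expect_identical(length(pls), 1L)
  expect_identical(regions(pls[[1]]), c("c1", "c2", "c3", "c4"))
  expect_identical(completeness(pls[[1]])[["4"]], 4L)
  sc <- scoreParalogon(pls[[1]], tab)
  expect_identical(unname(sc$totals["quartet"]), 4L)
  expect_equal(sc$consistency, 1.0)
})

test_that("detection is invariant to row order and chromosome relabeling", {
  sim <- simulateGenomeEvolution(simulationConfig(seed = 8, loss_prob = 0.2))
  rec <- as.data.frame(sim$table)
  fams <- suppressWarnings(filterFamilies(sim$table, "focal"))$retained
  run <- function(df) {
    tab <- genomeTable(df)
    g <- buildParalogonGraph(tab, "focal", fams)
    pls <- detectParalogons(g, tab, "focal", fams)
    lapply(pls, regions)
  }
  base <- run(rec)
  perm <- withr::with_seed(2, rec[sample(nrow(rec)), ])
  expect_identical(lapply(base, sort), lapply(run(perm), sort))
  # bijective relabeling of chromosomes: same sets up to the relabeling
  relab <- stats::setNames(paste0("K", seq_along(unique(rec$chromosome))),
                           unique(rec$chromosome))
  rec2 <- rec; rec2$chromosome <- unname(relab[rec$chromosome])
  got <- lapply(run(rec2), function(r) sort(names(relab)[match(r, relab)]))
  expect_setequal(lapply(base, sort), got)
})

test_that("oversized components are split with a translocation note", {
  # two true quartets glued together by heavy cross edges would exceed
  # max_regions = 4; the greedy split keeps intra-part weight high
  rows <- list()
  for (f in paste0("A", 1:3))
    for (chr in paste0("x", 1:4))
      rows[[length(rows) + 1L]] <- list("sp", paste0(f, chr), f, chr,
                                        1e6 * length(rows))
  for (f in paste0("B", 1:3))
    for (chr in paste0("y", 1:4))
      rows[[length(rows) + 1L]] <- list("sp", paste0(f, chr), f, chr,
                                        1e6 * length(rows))
  # two bridging families shared between x1 and y1
  rows[[length(rows) + 1L]] <- list("sp", "br1x", "BR1", "x1", 1e6)
  rows[[length(rows) + 1L]] <- list("sp", "br1y", "BR1", "y1", 2e6)
  rows[[length(rows) + 1L]] <- list("sp", "br2x", "BR2", "x1", 3e6)
  rows[[length(rows) + 1L]] <- list("sp", "br2y", "BR2", "y1", 4e6)
  tab <- toy_table(rows)
  fams <- c(paste0("A", 1:3), paste0("B", 1:3), "BR1", "BR2")
  g <- buildParalogonGraph(tab, "sp", fams)
  pls <- detectParalogons(g, tab, "sp", fams, min_shared = 2L,
                          max_regions = 4L)
  expect_identical(length(pls), 2L)
  expect_true(all(vapply(pls, function(p)
    length(p@translocation_note) > 0L, logical(1))))
  expect_setequal(lapply(pls, regions),
                  list(paste0("x", 1:4), paste0("y", 1:4)))
})

test_that("consistency degrades monotonically with translocation rate", {
  cons_at <- function(rate) {
    vals <- vapply(1:6, function(seed) {
      sim <- simulateGenomeEvolution(
        simulationConfig(seed = seed, loss_prob = 0,
                         transloc_rate = rate))
      fams <- suppressWarnings(
        filterFamilies(sim$table, "focal"))$retained
      g <- buildParalogonGraph(sim$table, "focal", fams)
      pls <- detectParalogons(g, sim$table, "focal", fams)
      mean(vapply(pls, function(p)
        scoreParalogon(p, sim$table)$consistency, numeric(1)),
        na.rm = TRUE)
    }, numeric(1))
    mean(vals, na.rm = TRUE)
  }
  c0 <- cons_at(0); c1 <- cons_at(0.05); c2 <- cons_at(0.2)
  expect_equal(c0, 1.0)
  expect_lte(c1, c0)
  expect_lt(c2, c1)
})

test_that("cross-species paralogons merge by family overlap", {
  mk <- function(sp, id, fams) new("Paralogon", paralogon_id = id,
    species = sp, regions = c("r1", "r2"),
    support = data.frame(family_id = fams, n_regions = 2L, pattern = ""),
    completeness = c(`4` = 0L, `3` = 0L, `2` = length(fams)),
    translocation_note = character())
  sets <- list(
    human = list(mk("human", 1L, c("f1", "f2", "f3"))),
    chicken = list(mk("chicken", 1L, c("f1", "f2", "f4")),
                   mk("chicken", 2L, c("g1", "g2"))))
  m <- mergeParalogons(sets)
  expect_identical(m$group[m$species == "human"],
                   m$group[m$species == "chicken" & m$paralogon_id == 1L])
  expect_false(m$group[m$species == "chicken" & m$paralogon_id == 2L] %in%
                 m$group[m$species == "human"])
})
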