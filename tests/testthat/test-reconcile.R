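test_that("duplication calls separate local from WGD pairs", {
  tab <- genomeTable(data.frame(
    species = "gar",
    gene_id = c("CHRNB1", "CHRNB1.2", "CHRNB2", "CHRNB4", "lone"),
    family_id = c("B1", "B1", "B245", "B245", "L"),
    chromosome = c("LG2", "LG2", "LG7", "LG9", "LG99"),
    start = c(1e6, 2e6, 5e6, 5e6, 1e6),
    end = c(1.1e6, 2.1e6, 5.1e6, 5.1e6, 1.1e6),
    strand = "+"))
  quartet <- new("Paralogon", paralogon_id = 1L, species = "gar",
                 regions = c("LG2", "LG7", "LG9", "LG11"),
                 support = data.frame(family_id = "B245", n_regions = 2L,
                                      pattern = "LG7,LG9"),
                 completeness = c(`4` = 0L, `3` = 0L, `2` = 1L),
                 translocation_note = character())
  # tandem pair on one chromosome in close proximity
  local <- classifyDuplication(c("CHRNB1", "CHRNB1.2"), list(quartet), tab)
  expect_identical(local$call, "local")
  expect_lte(local$evidence$distance_bp, 5e6)
  # pair on two regions of the quartet
  wgd <- classifyDuplication(c("CHRNB2", "CHRNB4"), list(quartet), tab)
  expect_identical(wgd$call, "WGD:1R/2R")
  expect_identical(wgd$evidence$paralogon_id, 1L)
  # neither criterion: different chromosomes, one outside the paralogon
  un <- classifyDuplication(c("CHRNB1", "lone"), list(quartet), tab)
  expect_identical(un$call, "unresolved")
  expect_error(classifyDuplication(c("CHRNB1", "nope"), list(), tab),
               "nope")
})

test_that("tree timing can veto a WGD call", {
  tab <- genomeTable(data.frame(
    species = "sp", gene_id = c("x1", "x2"), family_id = "x",
    chromosome = c("c1", "c2"), start = 1e6, end = 1.1e6, strand = "+"))
  p <- new("Paralogon", paralogon_id = 1L, species = "sp",
           regions = c("c1", "c2"),
           support = data.frame(family_id = "x", n_regions = 2L,
                                pattern = "c1,c2"),
           completeness = c(`4` = 0L, `3` = 0L, `2` = 1L),
           translocation_note = character())
  tree <- ape::read.tree(text = "((x1,x2)dup,(y1,y2)wgd)root;")
  # duplication node (dup) is not an ancestor of the horizon (wgd)
  veto <- classifyDuplication(c("x1", "x2"), list(p), tab, tree = tree,
                              wgd_horizon = "wgd")
  expect_identical(veto$call, "unresolved")
  ok <- classifyDuplication(c("x1", "x2"), list(p), tab, tree = tree,
                            wgd_horizon = "dup")
  expect_identical(ok$call, "WGD:1R/2R")
})

test_that("ancestral count and retention profile follow the groups", {
  g <- data.frame(group_id = c("x", "x", "x", "x", "y"),
                  gene_id = paste0("g", 1:5))
  expect_identical(ancestralCount(g), 2L)
  expect_identical(retentionProfile(g), c(`4` = 1L, `1` = 1L))
  expect_identical(maxLosses(g), 2L * 4L - 5L)
  # a fully retained quartet contributes no losses
  q <- data.frame(group_id = "q", gene_id = paste0("g", 1:4))
  expect_identical(maxLosses(q), 0L)
  # singletons only
  s <- data.frame(group_id = paste0("s", 1:5), gene_id = paste0("g", 1:5))
  expect_identical(retentionProfile(s), c(`1` = 5L))
  dup <- data.frame(group_id = c("x", "y"), gene_id = c("g1", "g1"))
  expect_error(ancestralCount(dup), "g1")
})

test_that("retention histogram matches simulated family sizes", {
  for (seed in c(5, 6)) {
    sim <- simulateGenomeEvolution(simulationConfig(seed = seed,
                                                    loss_prob = 0.3))
    groups <- data.frame(
      group_id = rep(names(sim$truth$ohnolog_groups),
                     lengths(sim$truth$ohnolog_groups)),
      gene_id = unlist(sim$truth$ohnolog_groups, use.names = FALSE))
    expect_identical(ancestralCount(groups),
                     length(sim$truth$ohnolog_groups))
    prof <- retentionProfile(groups)
    expect_identical(sum(prof), ancestralCount(groups))
    expect_identical(sum(prof * as.integer(names(prof))),
                     nrow(groups))
    # the bound never undercounts the recorded loss events, and is tight
    # for the surviving groups since all losses fall after the last round
    losses <- sim$truth$events
    n_losses <- sum(losses$event == "ohnolog_loss" &
                      sub("\\.0.*$", "", losses$gene_id) %in% groups$group_id)
    expect_gte(maxLosses(groups, rounds = 2L), n_losses)
    expect_identical(maxLosses(groups, rounds = 2L), n_losses)
  }
})

test_that("repertoire derivation enforces the ledger identity", {
  base <- repertoire("anc", paste0("g", 1:19))
  out <- lineageRepertoire(base, "derived", losses = c("g1", "g2", "g3"),
                           gains = "extra")
  expect_identical(repertoireCount(out), 17L)
  expect_true("extra" %in% repertoireGenes(out))
  expect_true(checkLedgerIdentity(base, out))
  # empty losses and gains are the identity
  same <- lineageRepertoire(base, "same")
  expect_identical(repertoireGenes(same), repertoireGenes(base))
  expect_error(lineageRepertoire(base, "bad", losses = "nope"), "nope")
  expect_error(lineageRepertoire(base, "bad", gains = "g5"), "g5")
  # unconfirmed losses are flagged in the ledger
  unc <- lineageRepertoire(base, "u", losses = c("g1", "g2"),
                           unconfirmed = "g2")
  led <- eventLedger(unc)
  expect_identical(led$unconfirmed[led$gene == "g2"], TRUE)
  expect_identical(led$unconfirmed[led$gene == "g1"], FALSE)
})

test_that("applying a WGD adds exactly the retained duplicates", {
  base <- repertoire("pre", paste0("g", 1:20))
  post <- applyWGD(base, "post", paste0("g", 1:11))
  expect_identical(repertoireCount(post), 31L)
  expect_true(all(paste0("g", 1:11, ".2") %in% repertoireGenes(post)))
  expect_identical(repertoireCount(applyWGD(base, "id", character())), 20L)
  expect_error(applyWGD(base, "bad", "nope"), "nope")
  expect_true(checkLedgerIdentity(base, post))
})

test_that("simulated duplication calls match truth at default rates", {
  agree <- vapply(1:5, function(seed) {
    sim <- simulateGenomeEvolution(
      simulationConfig(seed = seed, loss_prob = 0.2, local_dup_rate = 0.05))
    fams <- suppressWarnings(filterFamilies(sim$table, "focal"))$retained
    g <- buildParalogonGraph(sim$table, "focal", fams)
    pls <- detectParalogons(g, sim$table, "focal", fams)
    pc <- sim$truth$pair_calls
    calls <- vapply(seq_len(nrow(pc)), function(i)
      classifyDuplication(c(pc$gene_a[i], pc$gene_b[i]), pls,
                          sim$table)$call, character(1))
    mean(ifelse(calls == "local", "local",
                ifelse(calls == "WGD:1R/2R", "WGD", "unresolved")) ==
           pc$call)
  }, numeric(1))
  expect_gte(mean(agree), 0.95)
})
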