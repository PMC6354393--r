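aln_for <- function(...) {
  seqs <- c(...)
  new("ProteinAlignment", Biostrings::AAStringSet(seqs))
}

test_that("intron projection computes residue, phase and column", {
  # single-exon gene has no introns
  aln <- aln_for(g = strrep("A", 99))
  gm <- geneModel("g", cds = cbind(0, 300))
  expect_identical(nrow(projectIntrons(gm, aln)), 0L)

  # 100 nt before the intron: phase 1, interrupting codon 33
  gm2 <- geneModel("g", cds = rbind(c(0, 100), c(200, 400)))
  s <- projectIntrons(gm2, aln)
  expect_identical(s$phase, 1L)
  expect_identical(s$residue_index, 33L)
  expect_identical(s$column, 33L)

  # gaps shift the alignment column but not the residue index
  aln_g <- aln_for(g = paste0(strrep("-", 10), strrep("A", 99)))
  s2 <- projectIntrons(gm2, aln_g)
  expect_identical(s2$residue_index, 33L)
  expect_identical(s2$column, 43L)
})

test_that("minus-strand models project identically to plus-strand", {
  fx <- nachrFixture()
  L <- fx$protein_length
  aln <- aln_for(p = strrep("A", L), m = strrep("A", L))
  plus <- paralogon:::.fixtureGeneModel("p", c(2, 7, 12), fx$cluster_map,
                                        L, strand = "+")
  minus <- paralogon:::.fixtureGeneModel("m", c(2, 7, 12), fx$cluster_map,
                                         L, strand = "-")
  sp <- projectIntrons(plus, aln)
  sm <- projectIntrons(minus, aln)
  expect_identical(sp[, c("residue_index", "phase", "column")],
                   sm[, c("residue_index", "phase", "column")])
})

test_that("projection rejects inconsistent input", {
  aln <- aln_for(g = strrep("A", 50))   # wrong length for the CDS
  gm <- geneModel("g", cds = rbind(c(0, 100), c(200, 400)))
  expect_error(projectIntrons(gm, aln), "50")
  # intron inside the stop codon
  gm_stop <- geneModel("g", cds = rbind(c(0, 299), c(400, 401)))
  aln99 <- aln_for(g = strrep("A", 99))
  expect_error(projectIntrons(gm_stop, aln99), "stop codon")
  # protein not in the alignment
  expect_error(projectIntrons(geneModel("zz", cds = cbind(0, 300)), aln99),
               "zz")
})

test_that("clustering merges exact matches and reports near misses", {
  sites <- data.frame(
    gene_id = c("a", "b", "c", "d"), protein_id = c("a", "b", "c", "d"),
    residue_index = c(10L, 10L, 11L, 30L),
    phase = c(0L, 0L, 0L, 2L),
    column = c(10L, 10L, 11L, 30L))
  cl <- clusterIntronSites(sites)
  expect_identical(nrow(cl$clusters), 3L)
  expect_identical(cl$clusters$n_members, c(2L, 1L, 1L))
  # one near miss: columns 10 vs 11, same phase, not merged
  expect_identical(nrow(cl$near_misses), 1L)
  expect_identical(cl$near_misses$codon_shift, 1L)
  # a phase mismatch at adjacent columns is not a near miss
  sites$phase <- c(0L, 0L, 1L, 2L)
  expect_identical(nrow(clusterIntronSites(sites)$near_misses), 0L)
  # empty input
  expect_identical(nrow(clusterIntronSites(sites[0, ])$clusters), 0L)
})

test_that("clustering and matrix are invariant to gene input order", {
  fx <- nachrFixture()
  gm <- nachrGeneModels(fx)
  sites <- do.call(rbind, lapply(gm$models, projectIntrons,
                                 aln = gm$alignment))
  for (seed in 1:3) {
    perm <- withr::with_seed(seed, sample(nrow(sites)))
    cl1 <- clusterIntronSites(sites)
    cl2 <- clusterIntronSites(sites[perm, ])
    expect_identical(cl1$clusters, cl2$clusters)
    g <- sort(names(gm$models))
    expect_identical(buildPresenceMatrix(cl1, g),
                     buildPresenceMatrix(cl2, g))
  }
})

test_that("presence matrix conserves sites and handles partial genes", {
  sites <- data.frame(gene_id = c("a", "b"), protein_id = c("a", "b"),
                      residue_index = 5L, phase = 0L, column = 5L)
  cl <- clusterIntronSites(sites)
  m <- buildPresenceMatrix(cl, c("a", "b", "c"))
  expect_identical(dim(m), c(3L, 1L))
  expect_identical(sum(m, na.rm = TRUE), 2L)   # = number of sites
  expect_identical(m["c", 1], 0L)
  m2 <- buildPresenceMatrix(cl, c("a", "b", "c"), partial_genes = "c")
  expect_true(is.na(m2["c", 1]))
  aln <- aln_for(a = "AAAAAA", b = "AAAAAA")
  expect_error(buildPresenceMatrix(cl, c("a", "zz"), alignment = aln), "zz")
})

test_that("shared-intron accounting recovers group-level counts", {
  m <- rbind(g1 = c(1L, 1L, 0L), g2 = c(1L, 1L, 0L),
             h1 = c(1L, 0L, 1L))
  colnames(m) <- c("1", "2", "3")
  cs <- countSharedIntrons(m, list(G = c("g1", "g2"), H = "h1"))
  expect_identical(unname(cs$summary),
                   c(1L, 1L, 2L))   # all genes; >=2 groups; single group
  expect_identical(cs$per_cluster$n_groups, c(2L, 1L, 1L))
  expect_error(countSharedIntrons(m, list(G = "nope")), "nope")
})

test_that("motif annotation finds glycosylation sites and cysteine pairs", {
  aln <- aln_for(a = "NAS--", b = "NPS--", c = "CC--W", d = "CAAAC")
  ma <- annotateMotifs(aln)
  glyc <- ma[ma$kind == "n_glycosylation", ]
  expect_identical(glyc$gene_id, "a")          # NPS excluded (X = P)
  expect_identical(glyc$column, 0L)
  pair <- ma[ma$kind == "cysteine_pair", ]
  expect_identical(pair$gene_id, "c")          # adjacent CC pair
  expect_identical(pair$column_end, 1L)
  # d's cysteines are 4 residues apart: singles only at default tolerance
  expect_identical(sum(ma$gene_id == "d" & ma$kind == "cysteine"), 2L)
  expect_identical(sum(ma$gene_id == "d" & ma$kind == "cysteine_pair"), 0L)
  expect_identical(
    sum(annotateMotifs(aln, "d", max_pair_sep = 4L)$kind == "cysteine_pair"),
    1L)
  expect_error(annotateMotifs(aln_for(z = "AABZW")), "non-amino-acid")
})
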