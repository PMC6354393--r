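Package: paralogon
Title: Gene-Family Evolution Through Whole-Genome Duplications
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Reconstructs the history of a gene family against rounds of
    whole-genome duplication (tetraploidization) using three independent
    lines of evidence: intron positions projected onto a protein multiple
    sequence alignment and reconciled on a guide tree by Dollo parsimony,
    conserved-synteny paralogon detection from neighbour gene families,
    and repertoire accounting that separates tetraploidization-derived
    ohnologs from local (tandem) duplicates. Ships a forward simulator of
    genome evolution (tetraploidization, ohnolog loss, tandem duplication,
    translocation, intron gain and loss) with full truth records, and a
    packaged fixture encoding the vertebrate nicotinic acetylcholine
    receptor (nAChR) gene family.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    ape,
    igraph,
    jsonlite,
    withr,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
biocViews: Genetics, Phylogenetics, ComparativeGenomics, WholeGenomeSeq
RoxygenNote: 7.3.3
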