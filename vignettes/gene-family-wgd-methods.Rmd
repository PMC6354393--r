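---
title: "Reconstructing gene-family evolution against whole-genome duplications"
author: "paralogon package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing gene-family evolution against whole-genome duplications}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(paralogon)
```

## The problem

Early vertebrate evolution included two rounds of whole-genome duplication
(tetraploidization), conventionally called 1R and 2R, and a third round
(3R) on the stem of the teleost fishes. A gene family observed today is
therefore a palimpsest: some members are *ohnologs* (copies created by a
tetraploidization), others arose by local tandem duplication, and many
copies have been lost again. Sequence phylogenies alone often cannot
separate these histories because evolutionary rates vary strongly among
paralogs.

`paralogon` implements the three complementary lines of evidence used to
resolve such families, with the vertebrate nicotinic acetylcholine
receptor (nAChR) subunit genes as the packaged worked example:

1. **Intron positions.** Introns are projected into protein coordinates,
   mapped onto a common multiple sequence alignment, clustered by exact
   (column, splice phase) identity, and reconciled on a guide tree by
   Dollo parsimony.
2. **Conserved synteny / paralogons.** Chromosomal neighbourhoods around
   anchor genes are screened for gene families occurring on the same set
   of chromosomes; such chromosome sets (paralogons) are the footprint of
   chromosome-scale duplication.
3. **Repertoire accounting.** Presence/absence of family members across
   lineages is replayed as explicit loss/gain ledgers, so every count
   (ancestral genes, retained ohnologs, upper bounds on losses) is a
   reproducible arithmetic consequence of the input tables.

## Intron projection and clustering

For a CDS split into segments of lengths $l_1, \dots, l_k$ (transcription
order), the $j$-th intron sits after $n_j = \sum_{i \le j} l_i$ coding
nucleotides. Its splice **phase** is $n_j \bmod 3$ — the number of
nucleotides of the interrupted codon that lie 5' of the intron, with
phase 0 meaning the intron falls between codons — and the affected
residue is $\lfloor n_j / 3 \rfloor$ (0-based). The residue is mapped to
an alignment column by walking the gapped row, so intron homology can be
read off as column identity. All internal coordinates are 0-based,
half-open; GFF3 I/O converts to and from that format's 1-based inclusive
convention, and minus-strand genes are normalised to transcription order
before any arithmetic, which makes the projection strand-agnostic.

Two introns are called homologous only when **both** the alignment column
and the phase agree. Same-phase sites within `shift_tolerance` codons
(default 1) are reported as *near misses* but never merged: a one-codon
offset can arise from an intron-sliding mutation or from two independent
insertions, and the package deliberately surfaces the ambiguity rather
than resolving it. In the packaged nAChR fixture exactly one such pair
exists (published introns 12 and 17), and it stays unmerged.

## Dollo parsimony and alternative scenarios

Under Dollo parsimony a character (an intron cluster) is gained exactly
once and may be lost repeatedly. The gain is placed at the most recent
common ancestor of the carriers; the minimal loss set consists of the
maximal subtrees below the gain containing no carrier. The event cost is
$1 + \#\text{losses}$. Cells flagged *unknown* (partial gene models) are
uninformative: they neither demand a loss nor extend the gain clade.
Events are reported root-most first, which reads as an insertion order.

Because parallel insertion at the same position does occur,
`enumerateScenarios()` additionally enumerates every decomposition of the
presence pattern into disjoint independent gain clades (with minimal
losses inside each), keeping all scenarios within a cost slack (default
0) of the Dollo solution. Equal-cost scenarios are reported side by side
and never auto-resolved — e.g. the fixture's intron 4 admits either a
single basal gain followed by one loss, or two independent gains, both at
cost 2. Correctness of both reconstructions is pinned by brute-force
oracles in the test suite: exhaustive minimisation over all single-gain
loss subsets, and over all gain/loss edge labelings, on all patterns over
trees of up to six leaves.

## Paralogon detection

For a focal species, every retained neighbour family contributes weight 1
to each pair of chromosomes on which it has members. Edges supported by
fewer than `min_shared` families (default 2 — the published analyses rely
on visual congruence, so an explicit threshold had to be chosen; it is
configurable) are pruned, and the surviving connected components are the
paralogons. After a double tetraploidization a component is expected to
hold at most `max_regions = 4` chromosomes (8 after a third round);
larger components are split greedily so as to maximise intra-part edge
weight and annotated as translocations, mirroring how a single ancestral
region can be scattered over several present-day chromosomes.

Neighbour families enter this analysis only after curation: at least two
members in the focal species, a clear tree topology, strong node support,
an available outgroup and no excessive sequence conservation. The four
judgement flags are consumed from a curation table; automating the
underlying tree inspection is out of scope, since those calls are made by
eye on per-family phylogenies. When no curation table is given, all
families are retained and a warning is emitted.

Paralogons are detected per species and can be aligned across species by
Jaccard overlap (default $\ge 0.5$) of their supporting family sets.

## Duplication classification and repertoire arithmetic

A gene pair on one chromosome within `local_dist_bp` (default 5 Mb; the
biological statement is only "close proximity", so this is an explicit,
configurable cut-off) is a **local** duplication. A pair spanning two
regions of one paralogon is attributed to the corresponding WGD; a guide
tree plus a WGD horizon node can veto the call when the pair's
duplication node post-dates the tetraploidization. Everything else stays
**unresolved**.

Repertoire accounting is deliberately elementary: `ancestralCount()` is
the number of ohnolog groups, `retentionProfile()` the histogram of
post-WGD group sizes, and `maxLosses()` the bound
$a \cdot 2^{\text{rounds}} - g$ for $a$ ancestors and $g$ retained genes.
The bound assumes every loss happened after the final round; losses
between rounds remove two potential descendants at once, so the true
event count can be lower — for ohnolog pairs one cannot distinguish one
loss after 1R from two after 2R, and the package reports the bound, not
a resolution. `lineageRepertoire()` and `applyWGD()` replay explicit
ledgers and assert the count identity
(final = root + gains − losses) at every step. Genes that are merely
"not identified" in an assembly (e.g. possibly residing on unsequenced
GC-rich microchromosomes) are counted as losses but flagged
`unconfirmed` in the ledger.

Two pre-vertebrate tandem clusters are encoded as separate ohnolog groups
carrying a shared `tandem_parent` annotation, because the ancestral
repertoire counts them as distinct genes even though they arose from
local duplications before 1R.

## The packaged nAChR fixture

The fixture encodes the family's published structure as plain-text
tables: 10 ohnolog groups over the 19 post-2R genes; lineage ledgers
(human −3 genes → 16; chicken −4 → 15; spotted gar −1 +1 local duplicate;
teleost predecessor 20; 11 retained 3R duplicates → 31; zebrafish 7 →
27); and per-gene intron sets over 20 clusters whose totals are 3
universal introns, 6 shared by ≥2 of the four exon-intron groups and 14
group-confined. Gene structures are **synthetic**: exon sizes realise the
documented intron complements on a shared 460-residue protein, so that
projecting the emitted GFF3 against the emitted alignment reproduces the
intron matrix exactly. Splice phases are set to 0 throughout the fixture
because the published record specifies positions but not phases for most
introns; phase-dependent behaviour is exercised with simulated data
instead. Cluster numbering follows the published 1–20 labels via a
column/phase map (the numbering is not monotone in alignment column:
cluster 17 sits one codon after cluster 12 — the near-miss pair).
The fixture records the published fugu count of 28 genes while noting
that the supplementary material lists 29; fugu totals feed no computed
quantity. Chicken CHRNB1/CHRNE and a few similar absences are encoded as
`unconfirmed` losses.

## The simulator

`simulateGenomeEvolution()` forward-simulates a desk-scale genome: by
default 50 families laid out one gene per family on 5 chromosomes at 1 Mb
spacing (so a 10 Mb window holds ~21 genes, comparable to real gene
density at the scale of these analyses), a 1R+2R schedule, per-duplicate
loss probability 0.2, and optional tandem duplication and translocation.
Each WGD doubles every chromosome; fractionation draws one independent
survival per final duplicate, i.e. all losses are placed after the last
round — that makes the expected retained copies per family
$2^R(1-p)$ and renders the `maxLosses()` bound tight on simulated truth,
which is exactly what the corresponding tests assert. Truth records carry
the ohnolog groups, the daughter-chromosome set of every ancestral
chromosome, and the mechanism of every within-family pair.

`simulateIntronHistory()` gains each intron exactly once on a uniformly
chosen tree edge (Dollo by construction), loses it below the gain with a
per-edge rate, and can inject a second independent gain (`homoplasy`) on
a disjoint subtree. Intron positions are drawn at least two codons apart
so exact-match clustering is unambiguous. One identifiability caveat is
recorded in the truth tables: when losses prune an entire flank of the
gain clade, the MRCA of the surviving carriers — the *observable* gain
node — is more recent than the true one, and no reconstruction method can
recover the difference. Lossless simulations therefore check recovery of
the true gain node; lossy ones check the observable node.

The emitted alignments are gap-free and the synthetic protein alphabet is
a fixed 20-residue cycle: alignment inference and realistic sequence
evolution are out of scope, so passing tests demonstrate correctness of
the projection/clustering/reconciliation machinery, not robustness to
alignment error. All randomness flows from the single `seed` of
`simulationConfig()`; identical configurations yield byte-identical
output.

## Numerical and design choices

* Transcript choice in GFF3 input: longest CDS per gene, ties broken
  lexicographically by transcript ID.
* Stop codons are excluded from protein-length validation; an intron
  inside the stop codon is an error.
* Neighbour windows are anchored at the gene midpoint and closed
  (a midpoint exactly at distance `window_bp` is included).
* Scenario enumeration bounds the number of independent gains by the
  Dollo cost plus slack, which keeps the search exact and small.
* Problem sizes in the tests: brute-force oracles run over all presence
  patterns on trees of up to 6 leaves; simulation-based checks use 50–100
  families and 20 replicate seeds, which keeps the whole suite within a
  minute while leaving the binomial checks well-powered.

## Limitations

* Intron sliding beyond the one-codon near-miss report and nucleotide-
  level splice-site scanning are not automated.
* Curation flags for neighbour families are inputs, not computed.
* The simulator does not model chromosome fission/fusion beyond
  single-gene translocation, nor substitution processes.
* Cross-species paralogon merging is a greedy Jaccard heuristic intended
  for the small numbers of paralogons involved in family-scale analyses,
  not for genome-wide scans.
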