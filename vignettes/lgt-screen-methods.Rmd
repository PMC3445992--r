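---
title: "Screening archaeal genomes for inter-domain lateral gene transfer"
author: "phyloLGT"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening archaeal genomes for inter-domain lateral gene transfer}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phyloLGT)
```

## The problem

Archaea that live in bacteria-dominated niches — the human gut methanogens
*Methanosphaera stadtmanae* and *Methanobrevibacter smithii* are the model
case — acquire genes across the domain boundary by lateral gene transfer
(LGT). The phylogenomic way to detect such transfers is to build a
phylogeny for every protein in the genome and ask, gene by gene, who the
focal archaeon's closest relatives are on that tree. A gene whose tree
places the archaeon among bacteria, inside a diverse bacterial clade, is a
transfer candidate; a gene whose tree recovers the expected archaeal
sister is vertically inherited.

phyloLGT implements that screen end to end: per-tree classification with
direction and donor inference, reconciliation of verdicts from two tree
inference methods, codon-usage amelioration scoring, and ancestral
gene-family content reconstruction. Because the full genome-scale screen
depends on homolog databases that this package deliberately does not
touch, every stage comes with a synthetic-data generator that plants a
known history, so the machinery is testable at desk scale.

## Classifying a gene tree

A tree enters the classifier as an `AnnotatedGeneTree`: an ape phylogeny
whose leaves carry `(species, genus, phylum, domain)` records. Trees are
midpoint rooted by default — the upstream pipeline's rooting is rarely
recorded, and midpoint rooting is the standard surrogate; pass
`rooting = "asis"` in `screenConfig()` for pre-rooted trees.

The decision procedure inspects the sister group of the focal leaf:

1. a purely archaeal, non-companion sister means vertical inheritance
   (`non_LGT`);
2. a purely bacterial sister is an LGT candidate
   (`LGT_bacterial_neighbor`);
3. a sister consisting solely of companion-genus leaves (the focal
   taxon's nearest archaeal relative, *Methanobrevibacter* by default)
   triggers the *nesting test*: if the focal+companion clade sits inside
   a **bacterial clade** — successive enclosing levels whose added leaves
   are all bacterial and together span at least three phyla — the gene is
   an ancient transfer predating the divergence of the two genera
   (`LGT_nested_methanogen_pair`);
4. a purely eukaryotic sister is `LGT_eukaryote_neighbor`;
5. mixed-domain sisters are conservatively `non_LGT`, flagged
   (`mixed_sister`) for manual review rather than guessed at.

The three-phylum requirement for a bacterial clade guards against a
single mislabelled or contaminant neighbor: one bacterium adjacent to an
archaeon is weak evidence, bacteria from three phyla are not.

```{r classify-example}
cfg <- screenConfig(rooting = "asis")
tax <- data.frame(
    leaf_id = c("Focal", "BacF", "ArchA", "BacX", "BacY"),
    species = c("Methanosphaera_stadtmanae", "Clostridium_sp",
                "Methanosarcina_sp", "Bacteroides_sp", "Escherichia_sp"),
    genus = c("Methanosphaera", "Clostridium", "Methanosarcina",
              "Bacteroides", "Escherichia"),
    phylum = c("Euryarchaeota", "Firmicutes", "Euryarchaeota",
               "Bacteroidetes", "Proteobacteria"),
    domain = c("Archaea", "Bacteria", "Archaea", "Bacteria", "Bacteria"))
tr <- annotateTree(
    readNewick("((Focal:1,BacF:1)85:1,(ArchA:1,(BacX:1,BacY:1):1):1);",
               text = TRUE, geneId = "demo"), tax)
classifyTree(tr, cfg)[, 1:9]
```

### Direction of transfer

Direction is the subtle part. We call `bacteria_to_archaea` only when the
focal (or focal+companion) clade is *deeply* nested: at least two
successive purely bacterial enclosure levels meeting the phylum
threshold, **and** at least one archaeon elsewhere in the tree beyond the
enclosure. The second condition supplies polarity: with a single
bacterial level adjacent to the root, or with no archaea outside, the
topology is equally compatible with an export from archaea into bacteria,
so the direction stays `unknown`. The depth requirement
(`minDirectionLevels`, default 2) and the phylum threshold are
configurable.

`archaea_to_bacteria` is the mirror image — a small bacterial sister
group (at most `maxExportSisterSize` leaves, default 2) inside an
otherwise archaeal context. The archaeal context must span at least two
distinct non-companion archaeal genera; the taxonomy schema used here
carries genus as its finest rank below species, so genus diversity stands
in for the order-level diversity one would ideally require.
`eukarya_to_archaea` mirrors the bacterial import rule with eukaryotic
enclosures (no phylum threshold, since eukaryote phyla are optional in
the taxonomy).

Trees where the focal species and the companion genus are the *only*
archaea present get special treatment: direction cannot be polarised, but
a gene found nowhere else in Archaea while sitting among bacteria is
most parsimoniously a bacterial acquisition. The classifier records this
as `only_archaea` (a composition fact) and sets the
`only_archaea_rescue` flag when the direction is otherwise unknown; the
consensus stage promotes such genes to bacterial origin.

The bootstrap value reported per gene is that of the *inspected branch* —
the edge joining the focal (or focal+companion) clade to its sister —
binned into tiers: high (> 70), moderate (51–70), low (≤ 50). The screen's
tier definitions leave exactly 50 unassigned between "51–70" and
"below 50"; we bin 50 as low and expose the boundary
(`tierModerateLow`) for anyone who reads the gap the other way.

### Paralogs and other open choices

- Multiple focal leaves (paralogs) are classified independently; the
  per-gene verdict is LGT if any copy is, with the per-leaf table kept in
  the `"perLeaf"` attribute.
- The nesting search ascends without depth limit by default
  (`maxNestingLevels`), since a genuinely nested clade may be wrapped in
  several bacterial layers.
- Sister-group composition is always recorded verbatim
  (`sister_composition`), so mixed or borderline cases can be re-examined
  without rebuilding trees.

## Consensus between tree-inference methods

Distance-based (NJ) and likelihood-based (ML) trees disagree often enough
that the screen only trusts candidates recovered by both. `mergeClassifications()`
applies the congruence rules: `LGT_confirmed` needs LGT topologies from
both methods; a candidate seen by one method only is kept as
`LGT_nj_only` but never counted as confirmed; genes whose alignments were
too small for ML (fewer than four taxa) are `unresolved_too_few_taxa` and
excluded. The merged direction is the shared one, or the single resolved
one when the other method is agnostic; direct contradictions are flagged
`conflict` and excluded from origin totals — the original survey reported
no such case and prescribes no rule, so we surface rather than resolve
them.

`summarizeScreen()` aggregates merged records into candidate counts,
direction and donor-phylum histograms per method, and the raw
tier × direction × only-archaea cross-tabulation. The published groupings
of that survey can each be recomputed from the cross-tab; two are built
in: the NJ event total (bacteria-directed trees plus only-archaea
rescues) and the ML good-support count (direction-resolved trees at high
or moderate tier). `referenceScreenClassifications()` rebuilds per-gene
tables encoding the survey's printed category counts, and pushing them
through merge and summary reproduces its headline arithmetic (223
candidates among 1336 trees, 196 confirmed, 129 bacterial-origin genes,
135 inter-domain events, and so on) — this is exercised in the test suite
and the acceptance script. One caveat a careful reader will notice: the
survey's prose counts 12 only-archaea NJ trees in one place and 11 in its
tier arithmetic; the bundled tables encode 11, which is the value
consistent with the published totals (62 + 58 = 120).

## Codon amelioration: CAI and ENC

Transferred genes arrive with their donor's codon usage and only
gradually ameliorate toward the host's. Two standard measures quantify
this:

- **CAI** (codon adaptation index): the geometric mean of codon relative
  adaptiveness $w_c = f_c / \max_{c' \in syn(c)} f_{c'}$ computed from a
  highly expressed reference set (ribosomal proteins). Met, Trp and stop
  codons carry no synonymous signal and are excluded. Zero reference
  counts take a 0.5 pseudo-count before division — the standard
  convention, which keeps unused codons strictly positive. The reference
  genes themselves are excluded from background statistics, since they
  define the scale.
- **ENC** (effective number of codons): Wright's statistic, from the
  per-amino-acid codon homozygosity
  $\hat F = (n \sum p_i^2 - 1)/(n - 1)$ averaged within degeneracy
  classes, $ENC = 2 + 9/\bar F_2 + 1/\bar F_3 + 5/\bar F_4 + 3/\bar F_6$,
  clamped to $[20, 61]$. A gene using one codon per amino acid scores 20;
  uniform synonymous usage approaches 61 (the finite-sample estimate
  slightly overshoots and is clamped). Amino acids observed fewer than
  twice, or with $\hat F = 0$, are left out of their class mean; a
  missing three-fold class (Ile absent) is interpolated as
  $1/(2/\bar F_2 - 1/\bar F_4)$, falling back to $(\bar F_2+\bar F_4)/2$
  — both corrections Wright's treatment permits. The genetic code table
  is the bacterial/archaeal one (degeneracy classes 9×2, 1×3, 5×4, 3×6),
  and codons containing N are skipped and counted.

`backgroundAndFlags()` z-scores every gene against the genomic background
and flags outliers beyond ±2 SD (`low_CAI`, `high_ENC`, …): recent
transfers are expected low-CAI/high-ENC, ameliorated ancient transfers
indistinguishable from the background. The original INCA-based
computation is not documented down to its pseudo-count settings, so these
defaults are stated rather than claimed to match it bit for bit.

The generator `simulateCodingSequences()` draws each codon from the
mixture $\alpha \cdot host + (1-\alpha) \cdot donor$ within its amino
acid; $\alpha$ is the amelioration parameter. CAI against the host
reference rises monotonically in $\alpha$ (Spearman ρ ≈ 0.98 over an
α-grid at 50 genes × 250 codons per point in the acceptance run), and
ENC falls as codon bias sharpens — the two sanity properties the screen's
interpretation rests on. What the simulation does *not* model: amino-acid
composition bias, GC pressure, length variation, or within-gene usage
heterogeneity; passing these tests says the metrics behave correctly, not
that real genomes are this clean.

## Ancestral gene-family content

Gene-family (COG-style) presence/absence on a rooted species tree is
reconstructed by parsimony: `fitch` (unit costs), `dollo` (one gain at
the most recent common ancestor of the carriers, losses free below), or
`weighted` Sankoff parsimony with a configurable gain penalty. The
default penalty of 2 encodes that gain by transfer is rarer than loss —
gene content in these lineages is loss-biased. The method this stands in
for additionally weighs gene-family co-occurrence networks when placing
events; those co-evolution inputs are external resources by construction,
so this package's reconstruction is phylogeny-only, and is documented as
such a surrogate.

Numerical conventions: cost ties at the root resolve toward absence
(families are assumed gained later rather than ancestrally ubiquitous);
backtracking ties keep the parent's state, making output deterministic.
`branchDiff()` compares any node against any of its ancestors and returns
gained/lost family sets — the node-to-node comparisons such analyses
report. Node naming follows the input tree's labels (tips and internal
labels, or `node_<k>` fallbacks) rather than any fixed numbering, because
internal node numbers are an artifact of a particular tree file.

`simulatePresenceAbsence()` evolves families along the tree with
per-branch flip probabilities $1 - e^{-rate \cdot length}$ (defaults:
gain 0.2, loss 0.4 per unit branch length, ~200 families). Events are
never planted on the two root-adjacent branches: the outgroup then always
carries the root state, which is exactly the polarity an outgroup-rooted
reconstruction needs — without it, a single event next to the root is
unidentifiable in principle (gain on one side and root-presence-plus-loss
on the other explain the same data). With that convention, capped
single-event histories are recovered event-for-event by all three modes,
which the tests assert.

## Synthetic gene trees

`simulateGeneTree()` plants the five outcome scenarios of such screens —
vertical inheritance, recent bacterial transfer, ancient pre-divergence
transfer, eukaryotic transfer, archaeal export — and returns the expected
classification alongside the tree. Design choices worth knowing:

- Branch lengths are small (0.08–0.2) within the ingroup with a long
  (3.5) outgroup stem, so midpoint rooting provably lands on the stem and
  the classifier is exercised through its default rooting path, not
  around it.
- The planted inspected edge draws its bootstrap support from a truncated
  normal (default mean 85, sd 10, clamped to [0, 100]) so tier logic sees
  all three tiers; other edges get 90–100.
- Bacterial taxa cycle through a fixed palette of gut-relevant phyla
  (Firmicutes, Bacteroidetes, Proteobacteria, Actinobacteria, …), so
  donor-attribution output resembles real screens.
- Default taxon counts (6 bacteria over 3 phyla, 4 archaea, focal plus
  both companions) are the smallest configuration in which every rule —
  the three-phylum clade test, the two-level nesting depth, the
  two-genus export context — is non-trivially satisfiable; typical real
  trees are larger, not smaller.

These trees are noise-free by construction: the classifier must recover
100% of planted verdicts (the acceptance run checks 400 mixed trees), and
any failure is a bug, not sampling error. Conversely, perfect recovery
here says nothing about robustness to alignment error, long-branch
attraction or incomplete taxon sampling — those enter through the tree
builder, which this package treats as an input.

## Tree construction utilities

Neighbor joining is delegated to ape's Saitou–Nei implementation behind
`buildNJTree()`, which adds the screen's input contract (symmetry, zero
diagonal, triangle-violation flagging) and the usual negative-branch
convention (clamp to zero, move the deficit to the sibling edge). On
additive matrices NJ recovers the generating topology and branch lengths
to 1e-9, verified exhaustively over every unrooted topology with up to
six leaves. Bootstrap supports come from column resampling
(`ape::boot.phylo`) with a caller-supplied deterministic builder; because
resampling is over column indices only, supports are invariant to taxon
order under a fixed seed. Problem sizes in the tests (50-leaf round
trips, 123 exhaustive topologies, hundreds of simulated trees) were
chosen as the smallest that exercise each property convincingly.

## Known limitations

- The screen's sensitivity is bounded by its stringency: genes whose only
  archaeal neighbors are confounded by a third archaeal lineage (the
  *Methanosarcina* effect preserved in the bundled ABC-transporter table
  as `asterisk_note`) are systematically called non-LGT or
  direction-unknown. This is the documented, conservative behaviour.
- Midpoint rooting can misplace the root on trees with strong rate
  heterogeneity; use `rooting = "asis"` with externally rooted trees when
  that matters.
- The weighted-parsimony reconstruction ignores co-evolution between
  families; counts of gains and losses on real data will differ from
  co-evolution-aware methods.
- CAI/ENC are computed under the standard prokaryotic code only.
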