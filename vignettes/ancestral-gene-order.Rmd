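---
title: "Reconstructing ancestral gene order from hierarchical orthologous groups"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing ancestral gene order from hierarchical orthologous groups}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ancora)
```

## The problem

Extant genomes carry a record of their ancestors' chromosomal organization:
two genes that sit next to each other in many distantly related species were
most likely neighbours in their common ancestor. `ancora` turns that signal
into explicit ancestral gene orders. Its inputs are a rooted species tree,
gene coordinates for every extant genome (GFF3), and hierarchical
orthologous groups (HOGs, in OrthoXML). Because HOGs are nested by
taxonomic level, they define a *gene lineage graph*: one ancestral gene per
HOG per internal node, with each descendant gene linked to its parent gene
in its most direct ancestor, and duplications flagged where one parental
gene has several child lineages at the same level. The collection of gene
nodes at an internal level is the proxy for that ancestor's gene content.

## The model and its three phases

**Bottom-up propagation.** Traversing the tree leaves-to-root, every
adjacency between two genes of a child level is lifted to the parental
level whenever both endpoint genes have parents there. Weights count the
number of propagations from extant genomes, so an edge's weight always
equals the number of extant observed adjacencies in its support closure
(plus one per gain bridge, below). Edges whose endpoints collapse onto a
single parental gene — paralogues merging at their point of duplication —
vanish; edges mapping onto the same parental pair merge, weights summed.
A gene with no parent (a gene gained on that branch) is modelled as an
insertion between two older genes: a maximal run of parentless genes
flanked by two parented genes is bridged by a single weight-1 edge between
the flanks' parents. Runs at contig ends produce no bridge.

**Top-down filtering.** Propagation deliberately over-propagates: an
adjacency observed in one species is lifted all the way to the root of its
families' levels. Traversing root-to-leaves, an edge is retained at the
root only when at least two distinct child subtrees support it, and at any
other node when two children support it *or* its parental form was
retained. Weights play no role here; the criterion is purely topological
(Dollo-style parsimony: one gain, arbitrarily many losses). The root-most
retained node of each edge lineage is its *emergence*, used for dating;
extant adjacencies whose parental form was never retained emerge at their
own leaf. For single-copy families this procedure provably coincides with
Dollo parsimony with a single gain at the MRCA of the exhibiting leaves
(restricted to nodes where both genes exist); the test suite verifies the
equivalence by brute force on hundreds of random instances.

**Linearization.** After filtering, some genes still have more than two
neighbours (conflicts from orthology errors, tree errors, convergent
rearrangements). For each conflicting gene, the two neighbours with the
greatest *linear path weight* are kept — the sum of edge weights along the
path through that neighbour up to the first gene whose degree differs from
two — and the other edges are removed. Conflicting genes are processed in
decreasing order of their maximum incident edge weight (ties: total
incident weight, then gene uid); neighbour ties fall back to the direct
edge weight, then the neighbour uid. The exact processing order is a
design choice of this package: the published figure only states that an
order exists, and resolving the best-supported regions first with fully
deterministic tie-breaks makes runs reproducible. Cycles can survive
degree resolution (the underlying papers only require paths); each
residual cycle is broken at its minimum-weight edge. The result at every
internal node is a disjoint union of simple paths — ancestral contigs of
at least two genes; singleton genes are not reported as contigs.
Linearization at a node never looks at any other node's linearization.

**Orientation.** Extant adjacencies record which gene ends abut: same
strand reads head-to-tail, `+ -` head-to-head, `- +` tail-to-tail (the
classes are independent of the reading direction of a contig). Tallies of
the three classes accumulate during propagation, an edge's class is the
tally majority (ties: unknown), and per-gene strands are assigned along
each contig with the left end anchored to `+`. When an edge's class is
unknown the downstream strand is marked unknown and the walk re-anchors.
Bridged edges derive their class by walking the bypassed run: head-to-tail
preserves strand and head-to-head/tail-to-tail pin the absolute strands,
so the flanks' relative orientation is recoverable whenever the run is a
simple path with consistent majorities.

## Dating and phylostratigraphy

Every adjacency, ancestral or extant, carries its clade of emergence. With
a (possibly partial) node-age table, leaves are attributed age 0, nodes in
the table keep their age, and any remaining node receives the average of
its most recent aged ancestor and its oldest aged child, applied
iteratively from the root; a node with no aged ancestor anywhere is an
error listing the offenders. Per-node counts of gained, retained, lost and
duplicated adjacencies summarize chromosomal turnover. "Lost" demands that
both endpoint gene lineages survive at the node — otherwise the absence is
explained by gene loss, not rearrangement — and "duplicated" counts edges
merged from two or more child edges within a single child level; both are
documented interpretations, as the source method does not define these
categories formally. Cluster detection (used for histone-type tandem
arrays) reports maximal runs of more than four qualifying adjacencies with
fewer than ten genes between consecutive ones; both thresholds are
parameters.

## The simulator: a stated world

`simulate_evolution()` provides ground truth for every other module. A
Yule topology is grown to `n_leaves` by uniform leaf splitting with
exponential branch lengths (mean 1 by default). The root genome has
`root_genes` genes (default benchmarks use 1,000) on `root_contigs`
contigs with random strands. Along each branch, each event type occurs a
Poisson number of times with mean `rate × genome size at branch start ×
branch length`:

| event | low preset | harsh preset | effect |
|---|---|---|---|
| gain | 0.001 | 0.005 | new single-gene family at a uniform slot |
| loss | 0.001 | 0.005 | uniform gene deleted |
| tandem duplication | 0.0005 | 0.002 | copy inserted next to the source |
| dispersed duplication | 0.0002 | 0.001 | copy inserted at a uniform slot |
| inversion | 0.002 | 0.02 | segment reversed, strands flipped |
| translocation | 0.0005 | 0.005 | segment moved, possibly across contigs |

Rates are per gene per unit branch length. The low-rearrangement preset is
the package's stated benchmark world: at 1,000 genes it yields on the
order of five events per branch, a regime in which orthology would be easy
to infer and rearrangement signal is dominated by vertical inheritance —
the same spirit as simulating with a deliberately low mutation rate to
avoid confounding the gene-order benchmark with orthology errors.
Segment lengths for inversions and translocations are `1 + Geometric`
with mean 3 genes. Duplicating a gene that was itself gained on the same
branch creates an independent new family, since no parental gene exists to
anchor the paralogy; this corner case is rare at benchmark rates.

What the simulator does *not* emulate: sequence evolution (there are no
sequences at all), orthology-inference noise (the emitted HOGs are exact
truth), horizontal transfer, and chromosome fissions/fusions as explicit
events (translocation across contigs covers part of this space). A green
benchmark therefore establishes the correctness and calibration of the
gene-order algorithm under known gene lineages, not robustness to HOG
errors — the published experiments with inferred HOGs address the latter
and report slightly lower scores (98.9% precision / 96.8% recall harmonic
means), which this package's acceptance suite uses as lower bounds.

Ground truth is emitted in the same formats the pipeline consumes. Only
what ideal orthology inference could observe is written to OrthoXML:
lineages with no extant descendants are pruned, single-child chains are
collapsed (the reader re-materializes them), and duplications with a
single surviving copy lose their flag, which is exactly the information
loss a real HOG pipeline would suffer. Gene instances created and lost
within one branch belong to no node's genome and are excluded from truth
entirely.

## Evaluation protocol

Inferred ancestral genes are mapped to true ancestral genes per level by
greedy maximal overlap of descendant extant gene sets (ties broken by uid,
assignment injective both ways). An inferred adjacency is a true positive
when both endpoints map and the mapped pair is adjacent in the true
ancestral genome; precision is `100·TP/(TP+FP)`, recall `100·TP/(TP+FN)`,
aggregated across levels by the harmonic mean with equal weight per level
(whether the published aggregation weighted levels by size is not stated;
equal weighting is this package's choice). Undefined scores (no
predictions at a level) are reported as `NA` and excluded from harmonic
means. Masked-genome projection predicts an extant adjacency for every
adjacency of the direct ancestor whose two endpoints have exactly one
descendant each in the masked species; descendant paralogues cannot be
phased and block projection, which is why a lineage hit by a whole-genome
duplication projects essentially nothing.

## Numerical and degenerate-input choices

* All pair keys, edge ids and output rows are ordered by gene uid, so runs
  are bit-reproducible; the pipeline itself consumes no random numbers.
* A newick root with exactly three children is rejected as an unrooted
  tree; explicit multifurcations (including 4+ at the root) are accepted,
  and the two-children-minimum support rule applies to them unchanged.
* Group levels in OrthoXML may be given as `TaxRange` properties or
  implied (MRCA of the members). A group whose level is a leaf, repeats
  its parent's level, or contains species outside its clade is rejected.
* Flat groups (members from several species with no explicit intermediate
  group) are materialized by routing members down the species tree: one
  shared gene per intervening node per lineage, with `paralogGroup`
  members kept as separate lineages. Clades without members receive no
  gene — the HOG implies loss there.
* Genes in the GFF but not in the OrthoXML become singleton families;
  genes in the OrthoXML with no coordinates stay in the lineage but carry
  no adjacencies (both are counted in messages).
* The optional `min_weight` / `min_completeness` pre-filters (defaults
  off) drop low-evidence ancestral edges before parsimony filtering,
  mirroring the recommended mitigation for reticulate or noisy clades.

## Known limitations

Contiguity is deliberately sacrificed for precision: one missing adjacency
splits a chromosome into two contigs, and no scaffolding of contigs into
chromosomes is attempted. Adjacencies shared through horizontal transfer
or convergence are mis-dated to a common ancestor by construction. The
simulator's uniform event placement has no hotspots, so benchmark scores
should be read as upper bounds relative to real genomes with clustered
breakpoints.
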