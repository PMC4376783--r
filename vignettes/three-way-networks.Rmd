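---
title: "Three-way similarity networks from gene-family content"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Three-way similarity networks from gene-family content}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(threewaynet)
```

## The model

A pairwise similarity network over bacterial species answers the question
"which pairs of genomes share gene content?". Some biological signals are
not pairwise: three groups of species may share a block of gene families —
a metabolic module, a sporulation apparatus — whose joint presence is the
interesting observation, while each pairwise overlap is unremarkable
against the background of the core genome. `threewaynet` represents such
signals directly: a 3-way network is a 3-uniform hypergraph whose nodes are
species and whose hyperedges join species *triplets*, weighted by a triplet
similarity index.

All computation starts from the species–family (SF) count matrix: rows are
gene families (clusters of homologous genes produced upstream, e.g. by
Markov clustering of all-vs-all protein similarity), columns species, entry
*ij* the number of genes of family *i* in species *j*. The package does not
compute gene families from sequences; that is an upstream concern.

### The four indices

For binarized profiles (`bit = 1` iff count ≥ 1) the pairwise Sørensen
index is `2·Σ min / Σ sums`; the Czekanowski index is the same expression
on raw counts, so it sees copy-number differences the Sørensen index
ignores. The triplet Sørensen index, in Venn-region notation for a species
triple (A, B, C),

$$ S_3 = \frac{3}{2}\cdot\frac{ab + ac + bc - abc}{a + b + c}, $$

and the triplet Czekanowski index substitutes sums of elementwise pairwise
and triple minima of the raw counts. All four indices are in [0, 1],
symmetric in their arguments, and the count-based forms reduce exactly to
the presence/absence forms on binary input (a property the test suite
checks to 1e-12).

When a denominator vanishes (three empty genomes) the index is defined as
0 rather than NaN: empty profiles share nothing, and pruning treats weight
0 as no edge.

### Why 0.76 is the default threshold

Two bounds justify threshold pruning of triplet networks:

* if the triple intersection is empty (`abc = 0`), then `S3 ≤ 3/4`;
* if `Σᵢ min(Xᵢ, Yᵢ, Zᵢ) = 0`, then `C3 ≤ 3/4` (via the elementwise
  inequality `min(a,b) + min(a,c) − min(a,b,c) ≤ a`).

Both caps are attained (e.g. `x = (1,1,0)`, `y = (0,1,1)`, `z = (1,0,1)`
scores exactly 0.75), so 0.75 is the *minimum justifiable* threshold: any
threshold strictly above it retains only triplets whose weight provably
includes a three-way contribution. The package defaults to 0.76. Threshold
comparison is `weight ≥ t`, so a 0.75-exact edge survives `t = 0.75` but
not `t = 0.76`; this boundary convention is asserted in the tests. The test
suite proves the Sørensen bound exhaustively over all binary triples on a
4-family universe and probes the Czekanowski bound with 10,000 random
constrained triples; `scripts/acceptance.R` recomputes both numbers from
scratch.

## Pruning and combined networks

Three pruning operations are provided, all preserving the node set
(isolated species are retained in data files; dropping them is a viewer
concern):

* **Thresholding** (`prune_threshold`): keep edges with weight ≥ t.
* **Best-x edges** (`prune_best_edges`): per node, keep its x
  highest-weight incident edges and take the union over nodes — an edge
  kept for any member is kept. The networks discussed here use x = 2. Ties
  at the x-th rank are broken by the lexicographic order of the sorted
  member labels, making output deterministic.
* **Maximum spanning tree** (`max_spanning_tree`, pairwise networks only):
  invert weights to distances (`w' = 1 − w`) and take the minimum spanning
  tree. We implement Kruskal's algorithm with the same lexicographic
  tie-break; a deterministic tie-break matters because gene-content
  similarities are highly tied in practice (congeners often share identical
  profiles). Disconnected input yields a maximum spanning forest rather
  than an error. Correctness is checked against exhaustive enumeration of
  all spanning trees on small random networks and against igraph's MST.

An MST is maximally connected and minimally modular; a best-edge 3-way
network is modular but can leave genera mutually isolated.
`union_networks()` overlays the two (2-way edges and 3-way hyperedges
remain distinct objects even over the same species; conflicting duplicate
weights are an error), giving a backbone with local hyperedge structure.

## Enrichment and the bipartite view

`fisher_enrichment()` tests each (family, species) cell for
over-representation with a one-sided Fisher exact test on the gene-level
2×2 table `[[k, K−k], [n−k, N−K−n+k]]` (k = genes of the family in the
species, K = family total, n = species total, N = grand total); the p-value
is the hypergeometric upper tail, checked in the tests against a
closed-form summation oracle and `stats::fisher.test`. The table could
equally be built on presence/absence; gene counts are the SF matrix's
native unit, so gene-level is the default and `level = "presence"` is
offered. Holm–Bonferroni correction (step-down, α = 0.05) is applied over
all family × species tests jointly by default — one global procedure — with
`scope = "per_species"` as an alternative. Families significant in more
than one species ("shared-enriched") induce the bipartite family–species
network of `shared_enriched_network()`; every family node has degree ≥ 2 by
construction.

## Comparing 2-way and 3-way topology

For each genus, `genus_edge_stats()` counts inbound edges (all members
inside the genus — for a hyperedge, all three) and outbound edges (incident
with at least one member outside). Ratios are smoothed as
`(inbound + 1)/(outbound + 1)` because genera with zero outbound edges are
common after pruning and the raw ratio would be undefined; the pseudocount
keeps every genus rankable. `disagreement_scores()` ranks the ratios within
each network (descending — larger ratio, higher rank position — with
average ranks on ties; the direction is a convention and the absolute rank
difference is unaffected by reversing both) and reports per genus the
absolute rank difference `D_oi` (and `D_io` for the reciprocal ratio).
Genera linked by cross-genus hyperedges that pairwise networks miss swing
their outbound count in only one of the two networks and surface with the
largest scores. Any network pair may be supplied; best-edge 2-way vs
best-edge or thresholded 3-way is the intended use.

## Visualisation exports

No general-purpose viewer renders hyperedges, so `expand_for_viewer()`
rewrites each hyperedge {u, v, w} as an auxiliary *edge-node* of degree 3
linked to its members, carrying the hyperedge weight; pairwise edges pass
through. Edge-node ids are deterministic (`"e:" + sorted member labels`),
so exports diff cleanly across runs, and `collapse_expanded()` inverts the
transform exactly (a round-trip identity in the tests). `write_graph_file()`
emits SIF (interaction `tw` for edge-node links, `pw` for pairwise edges),
GraphML (via igraph, with node kind/genus/weight attributes) or a plain
edge list, plus a node-attribute TSV; genus colours are emitted as a
separate table (`genus_color_table()`, grey default for unmapped species)
rather than baked into graph files.

## The synthetic generator

`generate_sf()` emulates the block structure of a real SF matrix at desk
scale so every pipeline stage is testable without genome downloads:

* **core** families in every species (the shared housekeeping genome);
* **genus blocks** shared by all species of one genus;
* **private** families per species (strain-specific accessory genes);
* optional **bridge** families present in every species of one chosen
  genus pair — the ingredient that creates genuine 3-way, weak 2-way
  signal.

Family *presence* is deterministic given the design; gene *counts* of
present families are 1 + Poisson(mean), guaranteeing presence while giving
the Czekanowski indices non-binary structure. A single seed in the
configuration governs all randomness. Defaults — 2 genera × 4 species, 30
core, 40 genus, 10 private families, count mean 2 — model a small clade of
sequenced strains with a moderate accessory genome and give clean
separation: within-genus triplets score S3 = 0.875, cross-genus 0.625.
Adding `n_bridge = 60` raises cross-genus triplets to S3 ≈ 0.786 — over the
0.76 threshold — while within-genus pairwise similarity still dominates
cross-genus everywhere, so 2-way best-edge networks remain genus-separated.
That is the qualitative phenomenon of interest reproduced end-to-end:

```{r bridge}
mb <- generate_sf(synthetic_config(n_bridge = 60, seed = 1))
g <- genus_of(mb)
thr3 <- prune_threshold(build_network3(mb, "sorensen"), 0.76)
sum(g[thr3$species_a] != g[thr3$species_c])   # surviving cross-genus triplets
best2 <- prune_best_edges(build_network2(mb, "sorensen"), 2)
all(g[best2$species_a] == g[best2$species_b]) # pairwise stays separated
```

An optional elevated count mean for genus-block families
(`genus_mean_extra_count`) models lineage-expanded families; with a strong
expansion those families are recovered as significantly enriched in their
genus's species and appear in the shared-enriched bipartite network, which
the tests assert.

What the generator does *not* emulate: uneven genome sizes, family-size
power laws, horizontal transfer noise, annotation artefacts, or
phylogenetic correlation beyond the genus blocks. Passing tests on
synthetic data therefore demonstrate correctness of the algorithms under a
controlled signal, not robustness to every property of real pan-genome
matrices.

## Numerical and design choices

* Indices are computed in double precision with no internal tolerance;
  equality-sensitive behaviour (the 0.75/0.76 boundary) is exact because
  the attaining configurations produce exactly representable values.
* `build_network3()` caches pairwise sums of minima so each triplet costs
  one vectorised pass; the all-triplets network for 60 species (34,220
  hyperedges, the scale used in the tests' capacity check) builds in a few
  seconds, and the C(n, 3) count is verified exactly.
* Test problem sizes (random matrices of ≤ 20 families × ≤ 7 species,
  10,000-draw bound searches, 200 MST enumeration instances) are chosen so
  the full suite runs in well under a minute while still exercising every
  oracle; the scale check is the one deliberately larger case.
* The reciprocal-E-value pair score is kept as a small utility:
  `−log10((E_ab + E_ba)/2)` by default, clamped at 200 so aligner-reported
  `E = 0` underflows stay finite; a literal signed `log2` convention is
  available, since typeset renderings of this formula are ambiguous about
  base and sign. Negative E-values are rejected.
* SF matrices with families absent everywhere are retained (they contribute
  zeros); silently dropping rows would make round-trips lossy.
* Duplicate family or species labels are an error, never merged.

## Limitations

* Only triplet hyperedges are supported; no k-way generalisation.
* Hypergraph partitioning/clustering is out of scope; pruning is by
  threshold, best-x and MST only.
* The disagreement score is descriptive; no significance test is attached.
* Computing gene families (BLAST/MCL) and viewer layout/rendering are
  upstream and downstream concerns respectively.
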