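# threewaynet

Comparative genomics usually summarises the relationship between genomes
pairwise: compute a similarity between every pair of species, draw a graph,
prune it. Some relationships, however, are intrinsically *ternary* — three
clades sharing a block of gene families (say, a sporulation machinery) can
look unremarkable in every pairwise comparison while the three-way overlap
is striking. `threewaynet` models such relationships directly as **3-way
networks**: weighted 3-uniform hypergraphs over species, built from
gene-family content profiles, alongside the classical pairwise networks they
extend.

## The indices

Input is a species–family ("SF") count matrix: rows are gene families,
columns are species, entry *ij* is the number of genes of family *i* in
species *j*. Pairwise similarity uses the Sørensen index on binarized
profiles, or its count-aware analogue, the Czekanowski index:

    S2(X, Y) = 2 Σᵢ min(X_Bi, Y_Bi) / Σᵢ (X_Bi + Y_Bi)
    C2(X, Y) = 2 Σᵢ min(Xᵢ, Yᵢ)   / Σᵢ (Xᵢ + Yᵢ)

where `X_B` is the presence/absence vector of `X` (bit = 1 iff count ≥ 1).
The triplet forms weight hyperedges; in Venn-region notation (a, b, c the
per-species family totals; ab, ac, bc pairwise intersections; abc the triple
intersection):

    S3(A, B, C) = (3/2) · (ab + ac + bc − abc) / (a + b + c)

and `C3` is the identical expression on elementwise minima of raw counts.
All four indices live in [0, 1] and the triplet forms are invariant under
argument permutation.

Two theorems make thresholding principled: **if abc = 0 then S3 ≤ 3/4**, and
**if Σᵢ min(Xᵢ, Yᵢ, Zᵢ) = 0 then C3 ≤ 3/4**. Any threshold strictly above
0.75 (the package default is 0.76) therefore retains only triplets with a
genuine three-way intersection, not merely strong pairwise overlaps. The
package verifies both bounds by exhaustive enumeration and randomised search
in its test suite.

Around this core the package provides best-x-edge pruning, maximum spanning
trees (via `w' = 1 − w` inversion), 2-way ∪ 3-way combined networks,
gene-family enrichment networks (one-sided Fisher's exact test with
Holm–Bonferroni correction), a rank-based disagreement score between
pairwise and triplet genus topology, edge-node expansion for Cytoscape-style
viewers (SIF/GraphML), a block-structured synthetic SF-matrix generator, and
a CLI (`exec/threewaynet`).

## Worked example

```r
library(threewaynet)

m <- generate_sf(synthetic_config(seed = 1))   # 2 genera x 4 species
pruned <- prune_threshold(build_network3(m, "sorensen"), 0.76)
prune_report(pruned)
#> # A tibble: 1 × 4
#>   strategy  parameters edges_before edges_after
#>   <chr>     <chr>             <int>       <int>
#> 1 threshold t=0.76               56           8
head(tidy(pruned), 4)
#> # A tibble: 4 × 4
#>   species_a species_b species_c weight
#>   <chr>     <chr>     <chr>      <dbl>
#> 1 G1_s1     G1_s2     G1_s3      0.875
#> 2 G1_s1     G1_s2     G1_s4      0.875
#> 3 G1_s1     G1_s3     G1_s4      0.875
#> 4 G1_s2     G1_s3     G1_s4      0.875
```

Of the 56 possible triplets only the 8 within-genus ones survive the 0.76
threshold: cross-genus triplets score 0.625, below the theorem bound, so
they cannot carry a three-way intersection strong enough to pass. Now plant
60 "bridge" families shared across the two genera:

```r
mb <- generate_sf(synthetic_config(n_bridge = 60, seed = 1))
pb <- prune_threshold(build_network3(mb, "sorensen"), 0.76)
tidy(pb) |>
  dplyr::filter(substr(species_a, 1, 2) != substr(species_c, 1, 2)) |>
  head(3)
#> # A tibble: 3 × 4
#>   species_a species_b species_c weight
#>   <chr>     <chr>     <chr>      <dbl>
#> 1 G1_s1     G1_s2     G2_s1      0.786
#> 2 G1_s1     G1_s2     G2_s2      0.786
#> 3 G1_s1     G1_s2     G2_s3      0.786

best2 <- prune_best_edges(build_network2(mb, "sorensen"), 2)
g <- genus_of(mb)
table(within = g[best2$species_a] == g[best2$species_b])
#> within
#> TRUE
#>   10
```

Cross-genus triplets now score 0.786 and survive thresholding — yet the
2-way best-edge network is still entirely within-genus (all 10 edges): the
three-way link between the genera is invisible to pairwise analysis. This is
the qualitative phenomenon 3-way networks are built to expose.

Downstream, `enrich_families()` + `shared_enriched_network()` give the
bipartite shared-enriched-family view, `disagreement_scores()` ranks which
genera change topology most between network types, and
`expand_for_viewer()` + `write_graph_file()` emit SIF/GraphML with each
hyperedge as a degree-3 edge-node.

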