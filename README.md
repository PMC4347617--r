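# facpin

Fast agglomerative detection of functional modules in protein interaction
networks (PINs).

High-throughput interaction data yields large, noisy, approximately
scale-free networks in which functional modules and protein complexes
appear as dense subgraphs. `facpin` partitions such a network — weighted by
per-edge reliabilities in [0, 1] or unweighted — into non-overlapping
communities with a single greedy pass, and ships the quality functions,
benchmark-matching metrics and a planted-community simulator needed to
evaluate the result. It is aimed at systems-biology analysts clustering
PPI data and at methodologists benchmarking community detection on
planted-partition graphs.

## The method

The merge criterion is the **relative vertex-to-vertex clustering value**,
a local similarity premetric. With `N_u⁺ = N_u ∪ {u}` the augmented
neighborhood of `u`:

    R(u→v) = |N_u⁺ ∩ N_v⁺| / |N_u⁺|

and, on weighted graphs,

    Rw(u→v) = Σ_{a ∈ N_u⁺ ∩ N_v⁺} w*(u,a)·w*(a,v)  /  Σ_{b ∈ N_u⁺} w*(u,b)

with `w*` the edge weight and `w*(x,x) = 1` on the self-pair, so the
weighted form reduces exactly to the unweighted ratio on unit weights. The
score is deliberately asymmetric: by preferential attachment a low-degree
vertex is more likely to have joined its high-degree partner's community
than the reverse.

Clustering (`facpin_cluster`) starts from singleton clusters, visits
vertices in non-increasing order of weighted degree `κ_v`, and lets each
hub `v` absorb every still-unassigned neighbor `u` satisfying

    Rw(u→v) > 0.5·μ   and   Rw(u→v) ≥ Rw(v→u)

where `μ ∈ [0, 2)` is the merging parameter (default 0.5; larger μ is
stricter and yields more, smaller clusters). The pass runs in
`O(n·κ_ave²)` — linear in the vertex count at bounded average degree.

Partitions are scored with weighted modularity `Q`, the log-weighted
variant `Ω`, and modularity density `D` (`modularity_q`,
`modularity_omega`, `modularity_d`), and validated against known complexes
via the overlap score `O(C,K) = |C∩K|²/(|C|·|K|)` with threshold τ = 0.2
(`complex_match_stats`) and against functional categories via
recall/precision/F-measure (`module_category_scores`).

## Worked example

```r
library(facpin)

sim <- generate_planted_pin(planted_spec(community_sizes = rep(20L, 4L),
                                         p_in = 0.9, p_out = 0.02, seed = 42))
sim$graph
#> pin_graph: 80 vertices, 727 edges

p <- facpin_cluster(sim$graph, mu = 0.5)
p
#> pin_partition: 5 clusters over 80 vertices (max size 22, mean size 16.00)

rep <- modularity_report(sim$graph, p)
sprintf("Q = %.4f  Omega = %.4f  D = %.2f", rep$q, rep$omega, rep$d)
#> "Q = 0.6244  Omega = -1.2116  D = 34.08"

complex_match_stats(p, sim$complexes, tau = 0.2, min_size = 3)
#> match_report: 4 predicted vs 4 known complexes
#>   TP 4  FP 0  FN 0  perfect 2
#>   sensitivity 1.0000  specificity 1.0000  F-score 1.0000

mu_sweep(sim$graph, c(0.25, 0.5, 1.0, 1.5, 1.75))
#>     mu  k max_size  ave_size
#> 1 0.25  1       80 80.000000
#> 2 0.50  5       22 16.000000
#> 3 1.00  5       20 16.000000
#> 4 1.50  5       20 16.000000
#> 5 1.75 14       18  5.714286
```

The simulator plants four communities of 20 proteins; at μ = 0.5 the four
clusters of size ≥ 3 each match a planted community at overlap ≥ 0.2
(TP = 4, no false positives or negatives, so sensitivity, specificity and
F-score are all 1), two of them exactly. Q = 0.62 indicates strong
community structure, and the sweep shows the cluster count growing as the
threshold 0.5·μ tightens — one giant cluster at μ = 0.25, fragmenting
by μ = 1.75.

The same pipeline is scriptable from a shell via `exec/facpin`
(subcommands `cluster`, `sweep`, `evaluate`, `simulate`, `criteria`); real
data enters as a TSV edge list (`node_a  node_b  [weight]`), complexes as
`complex_id<TAB>member;member;...`, annotations as
`protein_id<TAB>category_id`.

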