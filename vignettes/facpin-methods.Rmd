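---
title: "Methods: agglomerative PIN clustering with a relative clustering premetric"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: agglomerative PIN clustering with a relative clustering premetric}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(facpin)
```

## The problem and the model

Protein interaction networks are large, sparse, approximately scale-free
graphs whose functional modules and protein complexes manifest as dense
subgraphs. Two features make clustering them awkward: interaction data
carries substantial false-positive noise, so edges deserve reliability
weights in $[0,1]$ rather than equal trust; and symmetric edge criteria
(triangle coefficients, common-neighbor ratios) habitually strand
low-degree peripheral proteins as separate clusters instead of attaching
them to the module they border.

`facpin` addresses both with an *asymmetric* local score. For a vertex $u$
with augmented neighborhood $N_u^+ = N_u \cup \{u\}$, the clustering value
of $u$ relative to $v$ is

$$R(u \to v) = \frac{|N_u^+ \cap N_v^+|}{|N_u^+|},$$

the fraction of $u$'s (augmented) neighborhood shared with $v$'s. It is a
premetric — self-similarity and maximality hold, symmetry does not — and
the asymmetry encodes preferential attachment: a pendant vertex scores 1
toward its hub while the hub scores much less toward it, so the pendant
joins the hub's module and not conversely. The weighted form replaces
set cardinalities with reliability products:

$$R_w(u \to v) = \frac{\sum_{a \in N_u^+ \cap N_v^+} w^*(u,a)\, w^*(a,v)}
                       {\sum_{b \in N_u^+} w^*(u,b)},$$

where $w^*$ is the edge weight on edges and $w^*(x,x) = 1$.

### The self-weight convention

A literal edges-only reading of the weighted numerator and denominator
would exclude the endpoint self-terms, and then the weighted form would
*not* reduce to $R(u \to v)$ on unit weights — the claimed specialization
would be off by an additive constant, and a pendant vertex would no longer
be maximal. We therefore adopt $w^*(x,x) = 1$ as the defining convention;
it is the unique choice under which the unweighted form is an exact
special case. Because the treatment of the endpoint terms in the weighted
formula has not, to our knowledge, been validated on real weighted PINs,
the strict edges-only variant remains available everywhere through
`strict_eq10 = TRUE` for side-by-side comparison.

## The merging rule and the algorithm

Vertex $u$ is merged into the current cluster $C(v)$ of $v$ when

$$R_w(u \to v) > 0.5\mu \quad\text{and}\quad R_w(u \to v) \ge R_w(v \to u),$$

with $\mu \in [0, 2)$ the user's merging parameter. We read $0.5\mu$ as a
product: it maps $\mu$'s range onto thresholds $[0,1)$, makes larger $\mu$
stricter (more, smaller clusters — the behavior the sweep statistics
show), and at $\mu = 1$ recovers the natural "more than half of $u$'s
neighborhood is shared" rule. The threshold comparison is strict and the
symmetry comparison non-strict, exactly as stated; when
$R_w(u \to v) = R_w(v \to u)$ the pair is merged provided the threshold is
cleared, which keeps tied equal-degree pairs (e.g. both endpoints of an
isolated edge) together.

`facpin_cluster` starts from singleton clusters, sorts vertices by
non-increasing weighted degree $\kappa_v$, and lets each hub in turn
absorb its passing neighbors. Three points in the pseudocode-level design
were genuinely open and are resolved as follows:

* **"Unassigned" means "still in a singleton cluster".** Every vertex
  starts in a cluster of size one, so reading "assigned" as "in any
  cluster" would forbid all merges. Under our reading, a processed hub
  that absorbed no one remains absorbable by a later hub — serving the
  stated goal of not stranding low-degree vertices — while members of
  grown clusters are never reassigned. A hub that has absorbed neighbors
  is itself fixed (its cluster has size ≥ 2); the underlying question of
  whether such a hub may later be absorbed is not settled by the method's
  description, and we chose the conservative answer.
* **Determinism.** Ties in $\kappa_v$ and neighbor iteration order are
  broken lexicographically by vertex id, and the final cluster labels
  follow first appearance over the sorted vertex list (label choice cannot
  affect membership). Identical inputs give identical partitions
  regardless of edge-list row order.
* **Separation of scoring from clustering.** The quality functions are not
  computed inside the clustering pass; `modularity_report` is composed
  after it (the CLI `cluster` subcommand does exactly that). Observable
  results are identical and each piece is testable alone.

One merging test costs $O(\kappa_{\max})$, so a full pass is
$O(n\,\kappa_{ave}^2)$ — effectively linear in $n$ for scale-free PINs
where the average degree is small. The test suite checks this contract
empirically: a ten-fold increase in vertex count at constant average
degree must increase runtime far less than the forty-fold a quadratic
method would suffer (we allow up to 25x).

## Partition quality functions

All three scores are built on the ordered-pair link weight
$L(S_1, S_2) = \sum_{u \in S_1, v \in S_2} w(u,v)$, under which an edge
interior to $S_1 \cap S_2$ counts twice and $L(V,V) = 2\sum_e w_e$. This
double-count convention is forced by Newman's $Q$: with
$e_{ii} = L(C_i, C_i)/L(V,V)$ and $a_i = L(C_i, V)/L(V,V)$, the coverage
fractions $a_i$ sum to 1 and the single-cluster partition scores
$Q = \sum_i e_{ii} - a_i^2 = 0$. The same $L$ is used consistently in
$\Omega = \sum_i e_{ii} \log a_i$ (natural log — the base only rescales
comparisons; note smaller $\Omega$ indicates stronger structure, so the
package reports it without a better/worse verdict) and in the modularity
density $D = \sum_i (L(C_i,C_i) - L(C_i,\bar C_i))/|C_i|$. Guard
conventions: $0 \cdot \log 0 := 0$ in $\Omega$, and all three scores are 0
on an edgeless graph. Degenerate denominators in the local criteria
(isolated vertices; pendant edges in the triangle coefficient) return 0
rather than erroring, because callers iterate these functions over every
edge and need them total.

## Evaluation metrics

Predicted modules of size ≥ 3 (the same minimum applied to gold-standard
complex catalogs) are scored two ways. Against known complexes, the
overlap score $O(C,K) = |C \cap K|^2/(|C||K|)$ with threshold $\tau = 0.2$
defines a match; TP counts matched predictions (once each, however many
complexes they hit), FN counts unmatched known complexes, FP unmatched
predictions, giving sensitivity $TP/(TP+FN)$, specificity $TP/(TP+FP)$
and their harmonic-mean F-score. Against functional categories, each
module receives recall $|C \cap F_i|/|F_i|$ and precision
$|C \cap F_i|/|C|$ for the category maximizing its F-measure (ties broken
by lexicographically smallest category id — the mapping rule is otherwise
unspecified and best-match is the standard convention); accuracy is the
mean F-measure. Enrichment $P$-values from annotation web services are
deliberately out of scope: their internal scoring is not reproducibly
specified. F-measures and F-scores with both components 0 are defined
as 0.

## The synthetic benchmark

`generate_planted_pin` draws a planted-partition graph: communities of
given sizes, intra-community edges with probability $p_{in}$,
inter-community edges with probability $p_{out}$, plus a layer of spurious
inter-community edges at rate `fp_rate` relative to the realized true-edge
count, with true and spurious reliability weights drawn from separate
ranges. This emulates what matters for correctness — community structure,
bridge edges, false-positive noise, reliability weighting — and ships its
own ground truth (partition, complex catalog, annotation catalog). It does
*not* emulate the skewed degree distributions, overlapping complexes or
hierarchical organization of real PINs, so passing recovery tests here
demonstrates algorithmic correctness on community-structured noise, not
biological performance on a specific interactome.

Defaults are four communities of 20 vertices, $p_{in} = 0.9$,
$p_{out} = 0.02$, no spurious edges, unit weights: dense enough that
planted modules are unambiguous, small enough that a twenty-replicate
recovery experiment runs in seconds. All randomness flows through one
integer seed into R's Mersenne-Twister generator, seeded locally so the
caller's RNG state is untouched; equal seeds give bit-identical graphs.
Inter-community edges are realized by drawing their count from the exact
binomial law and placing them uniformly — distributionally identical to
per-pair coin flips but scalable to the $10^4$-vertex graphs used in the
scaling check ($n = 10^3$ and $10^4$ as fifty and five hundred
communities of 20, with $p_{out}$ scaled to hold average degree constant).

## Parameters at a glance

| parameter | meaning | default | notes |
|---|---|---|---|
| `mu` | merge threshold scale, threshold is $0.5\mu$ | 0.5 | $[0, 2)$; larger = stricter, more clusters |
| `tau` | complex-match overlap threshold | 0.2 | $(0, 1]$; 1 demands perfect matches |
| `min_size` | smallest module evaluated | 3 | matches the gold-standard filter |
| `default_weight` | weight for unweighted edge lists | 1 | unweighted = all-ones weighting |
| `p_in`, `p_out` | planted edge probabilities | 0.9, 0.02 | $p_{in} \le p_{out}$ allowed as a structureless baseline |
| `fp_rate` | spurious edges per true edge | 0 | weights drawn from `w_false` |

## Known limitations

Clusters are non-overlapping, though real complexes share subunits;
directed interactions are not modeled; the greedy pass optimizes no global
objective, so modularity is a diagnostic, not a target; and the weighted
premetric's endpoint convention, while the only one consistent with the
unweighted special case, has not been validated against curated weighted
interactomes. The evaluation metrics score set overlap only — they know
nothing of annotation hierarchies or multiple testing.
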