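---
title: "Methods: seed-based PPI network analysis in seednet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: seed-based PPI network analysis in seednet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(seednet)
```

seednet re-implements, as tested R functions, the network-prioritization
workflow used to nominate drug targets from a panel of disease-associated
seed proteins: scored-network construction, topography and backbone
extraction, Markov clustering with switch detection, MCODE complex
detection, and gene-set over-representation analysis. This vignette is the
package's own account of each method, its assumptions, the tunable
parameters, and the numerical and design choices behind them.

## Network construction

The universe is an undirected simple graph with per-edge confidences in
[0, 1]. `read_edge_table()` accepts two score dialects — STRING-style
integer scores 0–1000 (divided by 1000) and unit-interval reals — collapses
duplicate unordered pairs keeping the **maximum** confidence (scored exports
are normally already deduplicated; max is the conservative merge), and drops
self-loops, since every downstream statistic assumes a simple graph.
Identifiers are uppercased and whitespace-stripped; synonym merges (such as
the fibrinogen protein/gene notation in the shipped seed panels) are applied
through an explicit alias table, never hard-coded.

`filter_by_confidence()` keeps edges with confidence ≥ τ. The default
τ = 0.400 is the conventional "medium confidence" minimum required
interaction score; the boundary is inclusive because a *minimum required*
score admits the minimum itself. Filtering never removes nodes: a seed that
loses all its edges remains an isolated node, so seed-set bookkeeping never
silently shrinks (real panels do contain singletons).

The zero-order network is the subgraph induced on the seeds. The first-order
network adds a fixed budget of `k_first_shell = 50` non-seed interactors,
chosen **per network** (not per seed): candidates are ranked by (1) number
of distinct seed neighbors, descending, (2) summed confidence over
seed-incident edges, descending, (3) identifier, ascending. Database
front-ends use their own internal ranking for this selection, which is not
reproducible offline; this ranking is deterministic, recoverable by a test
oracle, and — because it is per-network — yields the |seeds| + k node-count
identity that published seed expansions exhibit (15 + 50 = 65,
24 + 50 = 74). Second-shell expansion is deliberately refused
(`k_second_shell` must be 0) rather than silently ignored.

## Topography and backbone

`topology_report()` computes the NetworkAnalyzer-style statistics. Exact
identities: average degree 2m/n and density 2m/(n(n−1)). The mean local
clustering coefficient averages each node's neighborhood triangle density,
with degree < 2 nodes contributing 0. Diameter, radius, and characteristic
path length (mean hop distance over connected ordered pairs) are computed on
the **largest connected component** — published summaries report finite
values for networks that contain singletons, so singletons are evidently
excluded from distance statistics. Heterogeneity is the coefficient of
variation of the degree distribution, σ/μ with the population
(divide-by-n) variance — the NetworkAnalyzer convention; published reports
print values but no formula. Betweenness is hop-count shortest-path
betweenness with even splitting over equal-length paths, normalized by
(n−1)(n−2)/2 so a star center scores exactly 1; that normalization also
matches the magnitude of bottleneck values printed for ~65-node networks
(≈ 0.02–0.03). Edge confidences never influence distances: paths are
topological.

`extract_backbone()` returns the top `n_hubs = 6` nodes by degree (ties:
betweenness, then identifier) and the top `n_bottlenecks = 2` by betweenness
among the remaining nodes (ties: degree, then identifier) — the published
backbone convention of six hubs plus two non-hub bottlenecks.

`edge_enrichment()` asks whether the observed edge count exceeds what a
background density ρ would produce: expected = C(n,2)·ρ and the upper tail
of Binomial(C(n,2), ρ), floored at 10⁻¹⁶ to mirror the printed reporting
floor. Database nulls condition on global degree distributions, which are
unavailable offline; the binomial null is a deliberate, clearly labeled
approximation and its p-value is not comparable to database-reported ones.

## Markov clustering

`mcl()` implements the canonical MCL recurrence on the confidence-weighted
adjacency matrix. Self-loops are added first — by default each node receives
its maximum incident confidence (isolated nodes receive 1), which keeps the
transition matrix well-conditioned; a unit self-loop policy is also
available. The matrix is column-normalized and iterated: expansion (matrix
power, default 2), inflation (entrywise power r, renormalize), pruning of
entries below 10⁻⁵ (renormalize; a fully pruned column is re-anchored on its
own node), until the maximum absolute entry change falls below 10⁻⁸ or 200
iterations. Clusters are the connected components of the limit matrix's
symmetrized support, numbered by decreasing size then smallest member; a
component readout already partitions the nodes, so no attractor-overlap
tie-break is needed. Non-convergence returns a result flagged
`converged = FALSE` with a warning rather than an error.

Inflation is the granularity dial (the workflow's published settings are 3
and 3.4). A caveat that matters for sparse networks: on two planted blocks
of 20 nodes with intra-block edge probability 0.30 (mean intra-degree ≈ 5.7),
inflation 1.5 recovers the planted bipartition exactly, while inflation 3
shatters the blocks into many small clusters. This is inherent MCL behavior,
not an implementation artifact — an independent re-implementation of the
same recurrence produces identical cluster counts — and it is why the
package's recovery tests report the inflation scan rather than assuming one
setting fits all densities. Published networks that cluster cleanly at
inflation 3 are an order of magnitude denser (average degree ≈ 25).

## Switch detection

`find_switches()` scores every node v by its connections to *seed* members
of two chosen clusters: count the cluster-A seeds and cluster-B seeds
(excluding v itself) linked to v with confidence **strictly** greater than τ
(the published phrasing "confidence level > 0.4" is strict, unlike the
inclusive ≥ 0.400 build threshold; both are kept as written), and take
switch score = min(count_A, count_B) — the only reading under which a switch
needs connections *in both* clusters. Raw per-cluster counts are reported so
a one-sided reading remains recoverable, and the same counts at the 0.7 and
0.9 tiers are emitted as supplementary columns. Ranking is score, then total
seed connections, then identifier. All nodes are scored; callers that want
seed-only switch candidates can filter the table.

## MCODE complexes

`mcode_weights()` weights each node by the highest k-core of its closed
neighborhood: weight = k × (2m/(n(n−1))) of that core. `mcode_complexes()`
then repeatedly seeds at the highest-weight unvisited node (ties: smaller
identifier) and grows breadth-first, including neighbors whose weight is at
least (1 − vwp) × seed weight; included nodes are marked visited and never
reused, so complexes are node-disjoint. Haircut iteratively removes members
with fewer than two intra-complex connections (it may remove the seed node
itself); fluff (off by default) adds boundary neighbors whose
closed-neighborhood density exceeds `fluff_density`. Complexes below
`min_complex_size = 3` are dropped and the rest ranked by score =
density × size. Parameters default to the common Metascape configuration
(vwp 0.2, haircut on, fluff off) because the source workflow names the
algorithm without parameters. Weighting is topology-only — confidences are
ignored — per the published algorithm.

## Over-representation analysis

`hypergeom_tail(k, n, K, N)` is the accumulative hypergeometric tail
P(X ≥ k), summed in log space from exact log-binomial coefficients
(`lchoose` + log-sum-exp) so that tails near 10⁻⁵⁰ keep full relative
accuracy; the suite verifies it against direct distribution sums for every
configuration with N ≤ 25. `bh_fdr()` is the Benjamini–Hochberg step-up
(via `stats::p.adjust`), applied over exactly the emitted rows of each
collection — published tables adjust per collection.

`ora()` requires an **explicit** universe size N: the web tools behind
published tables use hidden universes, and back-solving their printed values
shows different tables used different N (the package's acceptance checks
use 20000 for the disease-annotation table and 14542 for the pathway
table, each inferred from the printed counts). When the collection
enumerates its universe, query genes outside it are dropped with a warning;
with only a declared size, the whole query is assumed annotated. Reported
per term: overlap k, ratio K/N, fold (k/n)/(K/N), strength log₁₀(fold), p,
and FDR, sorted by p, ties by fold then term id; `min_overlap = 3` (the
usual filter) is a flag, not a constant.

`kappa_term_clusters()` groups enriched terms whose membership patterns over
the query agree: Cohen's kappa between the binary overlap vectors, links at
kappa ≥ 0.3 (the conventional threshold; the boundary is inclusive),
clusters as single-linkage components, representative = lowest-p member.
The exact tree construction used by enrichment portals is unpublished;
single linkage on the kappa graph is the documented stand-in.

## Synthetic data: what it emulates and what it does not

`generate_network()` draws a planted two-community network: blocks of 20
and 20 with Bernoulli(0.30) intra-block and Bernoulli(0.02) inter-block
edges, intra confidences U(0.6, 0.99), inter confidences U(0.40, 0.70), 10
designated seeds per block, and 2 bridge nodes each wired to 3 distinct
seeds per block at confidence ≥ 0.7 — the planted switches. The block and
edge-probability settings are the package's fixed study conditions;
the seed counts and bridge wiring are chosen so that a bridge's guaranteed
min-side connection count (3) clearly exceeds the expected cross-community
seed links of a non-bridge node (0.02 × 10 = 0.2), giving an unambiguous
ground truth for switch detection. `generate_genesets()` plants terms that
draw ⌈purity × term_size⌉ = 20 of 25 genes from block 1 (purity 0.8)
among 50 uniform decoys in a 5000-gene enumerated universe.

The generator reproduces the *statistical shape* the methods assume —
communities, confidence tiers, bridges, enriched terms — but not real
interactome features: no empirical degree distribution or score calibration
(confidences are uniform), no hub-dominated topology, and densities an order
of magnitude below curated disease networks. Passing recovery tests
therefore demonstrate correctness of the machinery under known truth, not
performance claims about any particular database snapshot; reproducing a
specific published network requires that network's archived edge table.

## Problem sizes, determinism, degenerate inputs

The test suite and acceptance script run at deliberately small scale —
42-node synthetic networks, 20 generator replicates, brute-force oracle
comparisons on 50 random graphs with n ≤ 12, exhaustive hypergeometric
checks for N ≤ 25 — sizes at which independent enumeration oracles are exact
and the whole suite completes in well under a minute. Every stochastic step
takes an explicit integer seed; `run_pipeline()` reruns are byte-identical
except the manifest timestamp. Degenerate inputs are defined, not special
cases: τ = 1 yields an edgeless network whose MCL clustering is all
singletons; an empty GMT is a valid empty collection; a fully pruned MCL
column re-anchors on its own node; `k = 0` expansion equals the zero-order
network.

## Known limitations

* The binomial edge-count null understates the clustering induced by
  degree-conditioned database nulls; its p-values are approximations.
* MCL at high inflation shatters sparse communities (see above); inflation
  should be chosen per network density.
* ORA results are only as meaningful as the declared universe; with an
  unenumerated universe the query is assumed fully annotated, which is
  anti-conservative when many query genes are unannotated.
* Fluffed MCODE complexes may overlap; the default (fluff off) keeps
  complexes disjoint.
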