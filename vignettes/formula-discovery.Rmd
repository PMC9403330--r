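---
title: "Discovering multi-plant formula candidates on linked pharmacological networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discovering multi-plant formula candidates on linked pharmacological networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(herbnet)
```

## The problem

Traditional multi-plant herbal medicine (such as Indonesian Jamu)
combines several medicinal plants into one formula. A candidate
formula is plausible, from a network-pharmacology standpoint, when the
compounds its plants contain collectively interact with many of the
protein targets of a disease, and preferentially with the most central
ones. herbnet implements that reasoning as a concrete, exact
computation: it links plant, compound and protein networks, traverses
them into a weighted plant–protein bipartite graph, and then finds the
provably best compositions of exactly $k$ plants for a disease —
here parameterised throughout by the 21 target proteins of type II
diabetes mellitus (T2DM) shipped with the package.

## The three networks and how they are linked

Three undirected networks, stored as adjacency lists
(`tripartite_network`), describe the prior knowledge:

* **Network A** — plants, the compounds they contain
  (`plant_compound` edges, weight 1), and measured compound–protein
  interactions (`compound_protein` edges, weight 1).
* **Network B** — an extension of A with additional compounds that are
  close structural analogues of A's compounds, plus their own protein
  interactions.
* **Network C** — the disease proteins, each with a weight derived
  from its centrality in the human protein–protein interaction
  network, and the compounds known to interact with them.

Networks are joined by two mechanisms:

* **Structural similarity.** Compounds are encoded as fixed-length
  binary substructure fingerprints (4860 bits by default, the
  Klekota–Roth length) and compared with the Tanimoto coefficient
  $$\mathrm{coef} = \frac{c}{a + b - c},$$
  where $a$ and $b$ are the popcounts of the two fingerprints and $c$
  the number of shared 1-bits. A–B links are thresholded at 0.9
  (`threshold_links`); A–C links connect each disease-network compound
  to *all* reference compounds attaining its maximum similarity
  (`best_match_links`, ties kept). Two all-zero fingerprints get
  similarity 0 — the 0/0 form carries no structural evidence — with a
  warning. A best match of score 0 creates no edge, since a
  zero-weight edge could never contribute to traversal.
* **Protein identity.** Proteins are keyed by identifier (GI numbers),
  canonicalised by trimming, whitespace collapsing and case folding.
  Identical identifiers across networks denote the same protein;
  in the merged network they become a single node, which realises
  identity linking implicitly (`link_protein_identity` reports the
  shared identifiers explicitly when the networks are kept separate).
  Fuzzy protein similarity is deliberately not implemented: the
  linking procedure is exact identifier matching, and cross-database
  identifier conversion is expected to happen upstream.

Everything unreachable from the disease proteins is removed before
traversal (`prune_untraceable`), which leaves the smallest network
with the same answers.

## Protein weights

The disease proteins are weighted by averaging their betweenness (BC)
and closeness (CC) centralities and dividing by the maximum average
(`normalize_weights`), so weights lie in $(0, 1]$ and the most central
protein (INS, for the packaged T2DM table) has weight exactly 1.
Division by the maximum — rather than min–max scaling — is the
normalisation that reproduces the published weight table; min–max
would force the least central gene to 0. Reported values are rounded
half-up to 3 decimals; internal arithmetic is full precision. On the
packaged table the weights sum to ≈ 11.3, the maximum attainable
formula score.

```{r}
w <- normalize_weights(read_centralities(system.file(
  "extdata", "t2dm_protein_centrality.tsv", package = "herbnet")))
sum(w$norm)
```

## Traversal into the bipartite graph

`annotate_compounds` records, for every compound and every seed
protein, the best route weight from the protein to the compound. A
route crosses exactly one compound–protein interaction edge
(contributing 1.0) and may then hop along compound-similarity edges.
A direct interaction therefore contributes 1.0 and a
similarity-mediated route its similarity score; per compound and
protein the maximum over routes is kept (ties overwrite nothing —
updates are strictly greater-than). Routes crossing several
similarity edges multiply their scores; at the 0.9 threshold regime
this never matters for single-hop data but is the conservative choice
for chains. `backtrack_to_plants` then gives each plant, per protein,
the maximum edge weight over its compounds, yielding the weighted
plant–protein bipartite graph (`plant_profiles`).

## Scoring and the search

A candidate formula $S$ (a set of plants) scores
$$\mathrm{score}(S) = \sum_{i \in \mathrm{covered}(S)} P_i\, W_i(S),$$
where $P_i$ is the normalised weight of protein $i$ and $W_i(S)$ the
best edge weight any member plant has for it. Each protein counts
once, at the maximum over members — coverage by several plants is not
double-counted. This makes the score monotone and subadditive, two
properties the search bound relies on. A single plant's score is its
`total_value`, the "profit" used to order the search.

`complete_search` enumerates all $\binom{T}{k}$ subsets.
`branch_and_bound` explores a tree over plants sorted by descending
total value, with:

* **Branching** — *binary* (children: include / exclude the next
  plant) or *wide* (one child per remaining plant index).
* **Search strategy** — breadth-first (FIFO queue), depth-first
  (stack; the include branch is explored first, so high-value leaves
  are reached early), or best-first (priority queue). The best-first
  priority key is the node's optimistic bound by default; profit
  ordering is also available but degenerates at shallow levels, where
  profits are uninformative. Wide branching is paired only with
  breadth-first search.
* **Bound** — a node's bound is its profit plus the sum of the next
  $k - w$ still-eligible total values in sorted order. Subadditivity
  guarantees it dominates every completion; a fractional refinement is
  unnecessary because every "item" has unit weight.
* **Pruning** — a child is kept only while its bound exceeds the
  F-th best score retained so far ($-\infty$ until F candidates are
  held). Pruning against the single best score would be correct only
  for $F = 1$; pruning against the F-th best preserves the exact
  top-F. Candidates are kept in a bounded store where a new candidate
  replaces the worst only when strictly better.

Every strategy × branching combination returns the same ranked score
list as complete enumeration — this equivalence is the package's
central correctness property and is tested on hundreds of seeded
instances. When scores tie at the boundary of the retained list, the
*scores* are still identical across strategies but the specific tied
set retained may differ with encounter order; results are therefore
compared by ranked scores, plus plant sets whenever no tie touches
the list.

`dominance_filter` optionally removes plant X when some plant Y covers
a superset of X's proteins at per-protein edge weights at least X's.
This provably preserves the top-1 optimum (any formula using X scores
no better with X than with Y) but can alter lower-ranked candidates,
so it is off by default when `top_f > 1`. Among identical profiles
the lexicographically smallest plant id survives.

Telemetry (`nodes_generated`, `nodes_pruned`) quantifies search-space
reduction in hardware-independent terms: on a 100-plant instance with
$k = 3$ and heterogeneous total values, binary branch and bound
generates fewer nodes than wide branching, which generates fewer than
the 161,700 subsets of complete enumeration.

```{r}
pr <- generate_bipartite(n_plants = 100, n_proteins = 21, seed = 42)
bb <- branch_and_bound(pr, k = 3, top_f = 10)
attr(bb, "telemetry")
```

## The synthetic generator

`generate_networks` and `generate_bipartite` produce seeded, fully
reproducible instances so the complete pipeline is testable with no
database access. They emulate the *structure* the method consumes:
plants holding a handful of compounds; sparse fingerprints; a
fraction of compounds duplicated with small bit-flip noise calibrated
so the pair's Tanimoto similarity stays at or above 0.9 (extra bits
are capped at one-ninth of the popcount, the algebraic limit for
$n/(n+f) \ge 0.9$); 21 disease proteins with centralities drawn
uniformly on the ranges observed in the published table (BC on
[0, 0.35], CC on [0.3, 0.65]); and bipartite edge weights in the two
regimes traversal actually produces — 1.0 for direct interactions
(probability 0.5 by default), otherwise uniform on [0.9, 1). Every
disease protein receives at least one interacting compound so seeds
are never isolated.

What the generator does **not** emulate: the heavy-tailed degree
distributions of real compound databases, realistic fingerprint bit
correlations, or the scale of the real study (hundreds of plants,
thousands of compounds). Passing tests on synthetic data therefore
demonstrate the correctness of the algorithms — linking, traversal,
scoring, exactness and pruning behaviour of the search — not the
pharmacological validity of any particular formula on real data.

`generate_bipartite(planted_k = ...)` plants a provably unique optimal
composition: each planted plant exclusively covers its own block of
maximum-weight proteins at weight 1, and all decoy plants cover only
"light" proteins whose weights sum to half a block, so any $k$-set
that misses a planted plant forfeits a full block and can regain at
most half of one. Recovery of the planted set is thus guaranteed by
construction, making it a sharp end-to-end test of the optimiser.

## Numerical and design choices

* Duplicate edges keep the maximum weight, consistent with the
  keep-max updates used during traversal.
* Plant sorting breaks total-value ties lexicographically; output
  rankings sort by descending score, then lexicographic plant sets —
  identical inputs give byte-identical results.
* Display rounding is half-up (3 decimals for weights, 5 for scores);
  all comparisons and stored values are full precision.
* Problem sizes in the test suite are chosen for exhaustive
  cross-checking: oracle-equivalence sweeps use up to 15 plants and
  $k \le 4$ (where complete enumeration is trivially cheap), the
  pruning benchmark uses 100 plants, and property sweeps use dozens
  of seeded replicates.
* The combinatorial guard refuses complete searches beyond $10^7$
  subsets; branch and bound aborts past the same node budget.

## Limitations

* Identifier reconciliation across databases (CAS/CID/MGI/GI) is out
  of scope; inputs must arrive in a shared identifier scheme.
* Fingerprints are consumed precomputed; generating substructure bits
  from molecular structures is left to cheminformatics toolkits.
* The exact search is practical to $k \approx 4$ at realistic plant
  counts; larger compositions need the dominance filter or a
  different (heuristic) approach.
* Formula candidates are ranked by network coverage only;
  pharmacological validation of any suggested composition requires
  experimental follow-up.
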