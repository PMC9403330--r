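# herbnet

Exact discovery of multi-plant herbal formula candidates on linked
plant–compound–protein networks.

## What it does

Network pharmacology treats a candidate herbal formula as good when
the compounds contained in its plants collectively reach many of a
disease's protein targets, weighted by how central those targets are.
`herbnet` makes that idea computable end to end:

1. **Link** three networks — plants/compounds/proteins (A), a
   similarity-expanded compound extension (B), and disease
   proteins/compounds (C) — using the Tanimoto coefficient on binary
   substructure fingerprints,
   `coef = c / (a + b − c)`
   (threshold 0.9 for A–B, best-match with ties for A–C), and exact
   protein-identifier matching across networks.
2. **Weight** each disease protein by the average of its betweenness
   and closeness centralities, normalised by the maximum average
   (weights in (0, 1]).
3. **Traverse** from the disease proteins through interaction and
   similarity edges to every reachable compound, then back to plants,
   producing a weighted plant–protein bipartite graph: per plant and
   protein, the best route weight (1.0 for a direct interaction, the
   similarity score for a mediated route, maximum over routes).
4. **Search** for the top-F compositions of exactly k plants under the
   formula score
   `score(S) = Σ_i P_i · W_i(S)`
   (P_i protein weight, W_i best member edge weight, each protein
   counted once), with an exact branch-and-bound — breadth-first,
   depth-first or best-first strategies, binary or wide branching, and
   a lower-bound pruning rule — that returns provably the same ranked
   results as complete enumeration while generating far fewer nodes.

A seeded synthetic generator produces every input the pipeline
consumes, so the full stack runs and is tested without any database
access. The 21-gene type II diabetes centrality table used for
protein weighting ships in `inst/extdata/`.

## Worked example

```r
library(herbnet)

# protein weights from the packaged T2DM centrality table
w <- normalize_weights(read_centralities(system.file(
  "extdata", "t2dm_protein_centrality.tsv", package = "herbnet")))
sum(w$norm)
#> [1] 11.30673

# end-to-end on a seeded synthetic instance
cfg <- list(simulate = list(n_plants = 30, n_compounds = 90,
                            n_proteins = 21, seed = 7),
            search = list(k = 3, top_f = 5))
res <- run_pipeline(cfg)
#> [simulate] generated networks (seed 7)
#> [link] A-B threshold links (t = 0.90): 27
#> [link] A-C best-match links: 31
#> [link] merged network: 196 nodes, 413 edges
#> [prune] traceable subnetwork: 194 nodes, 412 edges
#> [traverse] annotated compounds: 136
#> [traverse] plants with a profile: 29
#> [search] top 5 of C(29, 3); nodes generated 1002, pruned 104
res$candidates
#> formula_candidates: top 5 compositions of 3 plants (brfs/binary)
#>  rank                                               plants k    score n_covered
#>     1 Plantus synth008; Plantus synth016; Plantus synth029 3 13.33499        21
#>     2 Plantus synth002; Plantus synth008; Plantus synth020 3 13.31705        21
#>     3 Plantus synth006; Plantus synth008; Plantus synth020 3 13.25080        20
#>     4 Plantus synth004; Plantus synth006; Plantus synth008 3 12.89316        20
#>     5 Plantus synth003; Plantus synth004; Plantus synth008 3 12.88897        20
#> nodes generated: 1002, pruned: 104
```

`sum(w$norm)` is the maximum attainable formula score on the packaged
protein table (≈ 11.3): the score a hypothetical composition would
reach by covering all 21 proteins at edge weight 1. In the synthetic
run, the best 3-plant composition covers all 21 simulated proteins
with score 13.33 (the synthetic protein table has its own weight sum),
and branch and bound found the exact top 5 after generating 1,002
nodes instead of scoring all C(29, 3) = 3,654 subsets.

The same search at 100 plants and k = 3 generates a few thousand
nodes against 161,700 complete-search evaluations, with identical
ranked results — the central exactness-plus-pruning property, tested
across all strategy × branching combinations on hundreds of seeded
instances.

A thin command-line wrapper with `simulate`, `link`, `traverse`,
`search` and `run` subcommands is installed at
`system.file("cli", "herbnet.R", package = "herbnet")`.

## Package layout

- `R/network.R` — tripartite network container, identity links,
  reachability pruning
- `R/similarity.R` — fingerprints, Tanimoto, threshold and best-match
  linking
- `R/protein_weighting.R` — centrality-based protein weights
- `R/traversal.R` — protein-to-compound annotation and backtracking
  to plants
- `R/scoring.R` — plant profiles and the formula score
- `R/optimizer.R` — branch and bound, complete search, dominance
  filter
- `R/synthetic.R` — seeded generators
- `R/io.R` — TSV/JSON readers and writers, end-to-end pipeline
- `vignettes/formula-discovery.Rmd` — the methods vignette
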