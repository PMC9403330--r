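# Shared fixtures, built in code.

# Three-plant toy bipartite graph with hand-computable scores:
# totals A = 0.9, B = 0.5, C = 0.75;
# pair scores {A,B} = 1.4, {A,C} = 1.15, {B,C} = 1.0.
toy_profiles <- function() {
  plant_profiles(data.frame(
    plant_id = c("A", "B", "C", "C"),
    protein_id = c("p1", "p2", "p1", "p2"),
    gene = c("P1", "P2", "P1", "P2"),
    protein_weight = c(1, 0.5, 1, 0.5),
    edge_weight = c(0.9, 1, 0.5, 0.5),
    stringsAsFactors = FALSE
  ))
}

# Published 21-gene disease protein centrality table.
t2dm_weights <- function() {
  normalize_weights(read_centralities(
    system.file("extdata", "t2dm_protein_centrality.tsv",
                package = "herbnet")))
}

# Random fingerprint with a guaranteed non-empty support.
random_fp <- function(id, nbits = 64, density = 0.3) {
  n_on <- max(1L, rbinom(1, nbits, density))
  fingerprint(id, sample.int(nbits, n_on), nbits = nbits, sparse = TRUE)
}

# Independent Tanimoto oracle via explicit set operations.
tanimoto_oracle <- function(fa, fb) {
  u <- union(fa$on, fb$on)
  if (length(u) == 0) return(0)
  length(intersect(fa$on, fb$on)) / length(u)
}

# Independent formula-score oracle: per-protein max over members, then
# a plain weighted sum over a long-format table.
score_oracle <- function(profiles, plants) {
  tab <- profiles$table[profiles$table$plant_id %in% plants, , drop = FALSE]
  if (nrow(tab) == 0) return(0)
  s <- 0
  for (p in unique(tab$protein_id)) {
    rows <- tab[tab$protein_id == p, , drop = FALSE]
    s <- s + rows$protein_weight[1] * max(rows$edge_weight)
  }
  s
}

# Enumerate all k-subsets and return their scores, descending
# (stable in lexicographic subset order for ties).
enumerate_scores <- function(profiles, k) {
  sets <- utils::combn(profiles$plants, k, simplify = FALSE)
  scores <- vapply(sets, function(s) score_oracle(profiles, s), numeric(1))
  ord <- order(-scores)
  list(sets = sets[ord], scores = scores[ord])
}
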