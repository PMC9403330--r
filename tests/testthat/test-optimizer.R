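test_that("plants sort by descending total value with lexicographic ties", {
  pr <- toy_profiles()
  expect_equal(names(sort_plants(pr)), c("A", "C", "B"))  # 0.9, 0.75, 0.5

  tied <- plant_profiles(data.frame(
    plant_id = c("zeta", "alpha"), protein_id = "p", gene = "P",
    protein_weight = 1, edge_weight = 0.9, stringsAsFactors = FALSE))
  expect_equal(names(sort_plants(tied)), c("alpha", "zeta"))

  set.seed(53)
  pr <- generate_bipartite(n_plants = 20, n_proteins = 10, seed = 53)
  ord <- names(sort_plants(pr))
  want <- pr$plants[order(-pr$totals, pr$plants)]
  expect_equal(ord, want)
})

test_that("the optimistic bound dominates every completion", {
  pr <- toy_profiles()
  # a full node's bound is its profit
  expect_equal(search_bound(pr, c("A", "B"), 2),
               formula_score(pr, c("A", "B"))$score)
  # root bound = 0.9 + 0.75, at least the enumerated optimum 1.4
  expect_equal(search_bound(pr, character(0), 2, level = 0), 1.65)
  expect_gte(search_bound(pr, character(0), 2, level = 0), 1.4)

  set.seed(59)
  for (rep in 1:10) {
    pr <- generate_bipartite(n_plants = 10, n_proteins = 8,
                             seed = 2000 + rep)
    k <- sample(2:4, 1)
    ord <- names(sort_plants(pr))
    for (trial in 1:5) {
      w <- sample(0:(k - 1), 1)
      level <- sample(w:(length(ord) - (k - w)), 1)
      chosen <- if (w > 0) ord[sample(seq_len(max(level, w)), w)] else character(0)
      b <- search_bound(pr, chosen, k, level = level)
      # enumerate all completions from the still-eligible tail
      tail_ids <- ord[seq.int(level + 1, length(ord))]
      combos <- utils::combn(tail_ids, k - w, simplify = FALSE)
      best <- max(vapply(combos, function(extra) {
        formula_score(pr, c(chosen, extra))$score
      }, numeric(1)))
      expect_gte(b + 1e-12, best)
    }
  }
})

test_that("complete search enumerates exactly choose(T, k) subsets", {
  pr <- toy_profiles()
  out <- complete_search(pr, 2, top_f = 3)
  expect_equal(attr(out, "telemetry")$nodes_generated, 3)
  expect_equal(out$score, c(1.4, 1.15, 1.0))
  expect_equal(attr(out, "sets")[[1]], c("A", "B"))

  pr10 <- generate_bipartite(n_plants = 10, n_proteins = 8, seed = 61)
  out <- complete_search(pr10, 3, top_f = 5)
  expect_equal(attr(out, "telemetry")$nodes_generated, choose(10, 3))
  expect_error(complete_search(pr10, 3, max_nodes = 10), "max_nodes")
})

test_that("branch and bound finds the toy optimum under every strategy", {
  pr <- toy_profiles()
  for (st in c("brfs", "dfs", "bfs")) {
    out <- branch_and_bound(pr, 2, top_f = 1, strategy = st)
    expect_equal(attr(out, "sets")[[1]], c("A", "B"))
    expect_equal(out$score, 1.4)
  }
  out <- branch_and_bound(pr, 2, top_f = 1, branching = "wide")
  expect_equal(attr(out, "sets")[[1]], c("A", "B"))

  single <- plant_profiles(data.frame(
    plant_id = "only", protein_id = "p", gene = "P",
    protein_weight = 1, edge_weight = 0.9, stringsAsFactors = FALSE))
  out <- branch_and_bound(single, 1, top_f = 1)
  expect_equal(attr(out, "sets")[[1]], "only")
  expect_equal(out$score, 0.9)
})

test_that("all strategy and branching combinations match complete search", {
  set.seed(67)
  for (rep in 1:20) {
    T <- sample(5:12, 1)
    k <- sample(1:min(4, T), 1)
    top_f <- sample(1:8, 1)
    pr <- generate_bipartite(n_plants = T, n_proteins = sample(5:12, 1),
                             seed = 3000 + rep)
    ref <- complete_search(pr, k, top_f = top_f)
    want <- enumerate_scores(pr, k)$scores
    # plant sets are only determined when no tie reaches the retained
    # list or its boundary; otherwise the retained candidate among
    # equals depends on encounter order
    f <- min(top_f, length(want))
    sets_determined <- !anyDuplicated(want[seq_len(f)]) &&
      (length(want) == f || want[f] != want[f + 1])
    combos <- list(c("brfs", "binary"), c("dfs", "binary"),
                   c("bfs", "binary"), c("brfs", "wide"))
    for (cb in combos) {
      got <- branch_and_bound(pr, k, top_f = top_f,
                              strategy = cb[1], branching = cb[2])
      expect_equal(got$score, ref$score,
                   info = sprintf("rep %d %s/%s", rep, cb[1], cb[2]))
      if (sets_determined) {
        expect_equal(attr(got, "sets"), attr(ref, "sets"))
      }
    }
    # ranked scores agree with the brute-force enumeration oracle too
    expect_equal(ref$score, utils::head(want, top_f))
  }
})

test_that("pruned searches generate no more nodes than the subset count", {
  pr <- generate_bipartite(n_plants = 40, n_proteins = 15, seed = 71)
  ref <- complete_search(pr, 3, top_f = 5)
  bnb <- branch_and_bound(pr, 3, top_f = 5)
  expect_equal(bnb$score, ref$score)
  expect_lt(attr(bnb, "telemetry")$nodes_generated,
            attr(ref, "telemetry")$nodes_generated)
})

test_that("search argument validation and edge cases behave", {
  pr <- toy_profiles()
  expect_error(branch_and_bound(pr, 5, top_f = 1), "exceeds")
  expect_error(branch_and_bound(pr, 2, strategy = "dfs",
                                branching = "wide"), "wide")
  expect_error(search_config(2, strategy = "dfs", branching = "wide"),
               "wide")
  # top_f above choose(T, k) returns every composition
  out <- branch_and_bound(pr, 2, top_f = 50)
  expect_equal(nrow(out), 3)
  out <- complete_search(pr, 2, top_f = 50)
  expect_equal(nrow(out), 3)
})

test_that("identical inputs give byte-identical results", {
  pr <- generate_bipartite(n_plants = 15, n_proteins = 10, seed = 73)
  a <- branch_and_bound(pr, 3, top_f = 5, strategy = "bfs")
  b <- branch_and_bound(pr, 3, top_f = 5, strategy = "bfs")
  expect_identical(a, b)
})

test_that("dominated plants are removed without changing the optimum", {
  dup <- plant_profiles(data.frame(
    plant_id = c("a", "b"), protein_id = "p", gene = "P",
    protein_weight = 1, edge_weight = 0.9, stringsAsFactors = FALSE))
  kept <- dominance_filter(dup)
  expect_equal(kept$plants, "a")  # lexicographically smallest survives

  strict <- plant_profiles(data.frame(
    plant_id = c("X", "Y", "Y"), protein_id = c("p1", "p1", "p2"),
    gene = c("P1", "P1", "P2"), protein_weight = c(1, 1, 0.4),
    edge_weight = c(0.5, 0.9, 0.3), stringsAsFactors = FALSE))
  expect_equal(dominance_filter(strict)$plants, "Y")

  expect_warning(out <- dominance_filter(dup, k = 2), "fewer than k")
  expect_equal(out$plants, c("a", "b"))

  set.seed(79)
  for (rep in 1:10) {
    pr <- generate_bipartite(n_plants = 15, n_proteins = 6,
                             seed = 4000 + rep)
    full <- complete_search(pr, 2, top_f = 1)
    # skipped filtering (too few survivors) is a valid outcome here
    red <- complete_search(suppressWarnings(dominance_filter(pr, k = 2)),
                           2, top_f = 1)
    expect_equal(red$score[1], full$score[1])
  }
})

test_that("best-first search works with either priority key", {
  pr <- generate_bipartite(n_plants = 12, n_proteins = 8, seed = 83)
  ref <- complete_search(pr, 3, top_f = 4)
  for (key in c("bound", "profit")) {
    got <- branch_and_bound(pr, 3, top_f = 4, strategy = "bfs",
                            bfs_key = key)
    expect_equal(got$score, ref$score)
  }
})
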