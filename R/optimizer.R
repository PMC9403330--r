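#' Exact top-F search for k-plant formula candidates
#'
#' Finds the `top_f` highest-scoring compositions of exactly `k`
#' plants, either by exhaustive enumeration of all `choose(T, k)`
#' subsets ([complete_search()]) or by branch and bound
#' ([branch_and_bound()]) with a lower-bound pruning rule that provably
#' returns the same ranked results while generating far fewer nodes.
#'
#' Plants are first sorted by descending total value (ties broken
#' lexicographically by plant id).  A partial solution's optimistic
#' bound is its profit plus the sum of the next `k - w` still-eligible
#' total values in sorted order; because the formula score is
#' subadditive and each plant's marginal gain is at most its total
#' value, this never underestimates the best completion.  A child node
#' is kept only while its bound exceeds the score of the F-th best
#' candidate held so far (`-Inf` until F candidates are held), so
#' pruning is exact for any F, not only for the single best.
#'
#' @name optimizer
NULL

#' Sort plants by total value
#'
#' Descending by total value; ties broken lexicographically by plant id
#' for reproducibility.
#'
#' @param profiles a [plant_profiles()] object.
#' @return Named integer vector: indices into `profiles$plants`, names
#'   are the plant ids in search order.
#' @export
sort_plants <- function(profiles) {
  stopifnot(inherits(profiles, "plant_profiles"))
  if (length(profiles$plants) == 0) stopf("no plant profiles to sort")
  ord <- order(-profiles$totals, profiles$plants)
  structure(ord, names = profiles$plants[ord])
}

# Precomputed search workspace in rank space (plants in search order).
#' @keywords internal
#' @noRd
bnb_prep <- function(profiles, k) {
  ord <- sort_plants(profiles)
  list(
    ids = names(ord),
    ER = profiles$E[, ord, drop = FALSE],
    pw = profiles$proteins$weight,
    totals = unname(profiles$totals[ord]),
    cs = c(0, cumsum(unname(profiles$totals[ord]))),
    T = length(ord),
    k = k
  )
}

# Sum of totals at sorted positions (from+1)..(from+n); caller ensures
# from + n <= T.
#' @keywords internal
#' @noRd
next_totals_sum <- function(prep, from, n) {
  prep$cs[from + n + 1] - prep$cs[from + 1]
}

#' Optimistic bound of a partial solution
#'
#' The bound of a partial composition is its current score plus the sum
#' of the total values of the next `k - length(chosen)` plants still
#' eligible in sorted order.  It never falls below the true score of
#' the best completion.
#'
#' @param profiles a [plant_profiles()] object.
#' @param chosen character vector of already-chosen plant ids.
#' @param k target composition size.
#' @param level number of sorted plants already considered (defaults to
#'   the highest sorted rank among `chosen`); eligible plants are those
#'   ranked after `level`.
#' @return The bound, or `-Inf` if fewer than `k - length(chosen)`
#'   plants remain eligible.
#' @export
search_bound <- function(profiles, chosen, k, level = NULL) {
  prep <- bnb_prep(profiles, k)
  chosen <- unique(as.character(chosen))
  r <- match(chosen, prep$ids)
  if (anyNA(r)) stopf("unknown plant id(s) in chosen set")
  if (length(r) > k) stopf("more than k plants chosen")
  if (is.null(level)) level <- if (length(r) == 0) 0L else max(r)
  need <- k - length(r)
  if (prep$T - level < need) return(-Inf)
  profit <- formula_score(profiles, chosen)$score
  profit + next_totals_sum(prep, level, need)
}

# ---- containers ------------------------------------------------------

#' @keywords internal
#' @noRd
fifo_new <- function() {
  e <- new.env(parent = emptyenv())
  e$items <- vector("list", 64)
  e$head <- 1L
  e$tail <- 0L
  e
}

#' @keywords internal
#' @noRd
fifo_push <- function(e, x) {
  e$tail <- e$tail + 1L
  if (e$tail > length(e$items)) length(e$items) <- 2L * length(e$items)
  e$items[[e$tail]] <- x
  invisible(e)
}

#' @keywords internal
#' @noRd
fifo_pop <- function(e) {
  x <- e$items[[e$head]]
  e$items[e$head] <- list(NULL)
  e$head <- e$head + 1L
  x
}

#' @keywords internal
#' @noRd
stack_new <- function() {
  e <- new.env(parent = emptyenv())
  e$items <- vector("list", 64)
  e$top <- 0L
  e
}

#' @keywords internal
#' @noRd
stack_push <- function(e, x) {
  e$top <- e$top + 1L
  if (e$top > length(e$items)) length(e$items) <- 2L * length(e$items)
  e$items[[e$top]] <- x
  invisible(e)
}

#' @keywords internal
#' @noRd
stack_pop <- function(e) {
  x <- e$items[[e$top]]
  e$items[e$top] <- list(NULL)
  e$top <- e$top - 1L
  x
}

# Max-heap on (key desc, seq asc): ties resolved by insertion sequence
# so best-first expansion is deterministic.
#' @keywords internal
#' @noRd
heap_new <- function() {
  e <- new.env(parent = emptyenv())
  e$keys <- numeric(0)
  e$seqs <- integer(0)
  e$items <- list()
  e$n <- 0L
  e
}

#' @keywords internal
#' @noRd
heap_less <- function(e, i, j) {
  # TRUE when i has lower priority than j
  e$keys[i] < e$keys[j] ||
    (e$keys[i] == e$keys[j] && e$seqs[i] > e$seqs[j])
}

#' @keywords internal
#' @noRd
heap_push <- function(e, key, seq, x) {
  e$n <- e$n + 1L
  i <- e$n
  e$keys[i] <- key
  e$seqs[i] <- seq
  e$items[[i]] <- x
  while (i > 1L) {
    p <- i %/% 2L
    if (heap_less(e, p, i)) {
      e$keys[c(p, i)] <- e$keys[c(i, p)]
      e$seqs[c(p, i)] <- e$seqs[c(i, p)]
      tmp <- e$items[[p]]; e$items[[p]] <- e$items[[i]]; e$items[[i]] <- tmp
      i <- p
    } else break
  }
  invisible(e)
}

#' @keywords internal
#' @noRd
heap_pop <- function(e) {
  x <- e$items[[1L]]
  n <- e$n
  e$keys[1L] <- e$keys[n]
  e$seqs[1L] <- e$seqs[n]
  e$items[[1L]] <- e$items[[n]]
  e$items[n] <- list(NULL)
  e$keys <- e$keys[-n]
  e$seqs <- e$seqs[-n]
  e$n <- n - 1L
  i <- 1L
  while (TRUE) {
    l <- 2L * i
    r <- l + 1L
    big <- i
    if (l <= e$n && heap_less(e, big, l)) big <- l
    if (r <= e$n && heap_less(e, big, r)) big <- r
    if (big == i) break
    e$keys[c(big, i)] <- e$keys[c(i, big)]
    e$seqs[c(big, i)] <- e$seqs[c(i, big)]
    tmp <- e$items[[big]]; e$items[[big]] <- e$items[[i]]; e$items[[i]] <- tmp
    i <- big
  }
  x
}

# Bounded top-F candidate store.  When full, a new candidate replaces
# the current worst only if strictly better; worst_retained is the
# pruning threshold (-Inf until F candidates are held).
#' @keywords internal
#' @noRd
topf_new <- function(top_f) {
  e <- new.env(parent = emptyenv())
  e$top_f <- top_f
  e$scores <- numeric(0)
  e$sets <- list()
  e
}

#' @keywords internal
#' @noRd
topf_worst <- function(e) {
  if (length(e$scores) < e$top_f) -Inf else min(e$scores)
}

#' @keywords internal
#' @noRd
topf_insert <- function(e, score, set) {
  if (length(e$scores) < e$top_f) {
    e$scores[length(e$scores) + 1L] <- score
    e$sets[[length(e$sets) + 1L]] <- set
  } else {
    i <- which.min(e$scores)
    if (score > e$scores[i]) {
      e$scores[i] <- score
      e$sets[[i]] <- set
    }
  }
  invisible(e)
}

# ---- result assembly -------------------------------------------------

#' @keywords internal
#' @noRd
assemble_candidates <- function(profiles, prep, q, telemetry, config) {
  sets <- lapply(q$sets, function(r) sort(prep$ids[r]))
  key <- vapply(sets, paste, character(1), collapse = "\r")
  ord <- order(-q$scores, key)
  sets <- sets[ord]
  scores <- q$scores[ord]
  covered <- lapply(sets, function(s) formula_score(profiles, s)$covered)
  out <- data.frame(
    rank = seq_along(sets),
    plants = vapply(sets, paste, character(1), collapse = "; "),
    k = rep(config$k, length(sets)),
    score = scores,
    n_covered = lengths(covered),
    stringsAsFactors = FALSE
  )
  structure(out,
            sets = sets, covered = covered,
            telemetry = telemetry, config = config,
            class = c("formula_candidates", "data.frame"))
}

#' @keywords internal
#' @noRd
validate_search_args <- function(profiles, k, top_f) {
  stopifnot(inherits(profiles, "plant_profiles"))
  if (k < 1 || k != round(k)) stopf("k must be a positive integer")
  if (top_f < 1 || top_f != round(top_f)) {
    stopf("top_f must be a positive integer")
  }
  if (k > length(profiles$plants)) {
    stopf("k = %d exceeds the number of plants (%d)",
          k, length(profiles$plants))
  }
}

# ---- complete search -------------------------------------------------

#' @rdname optimizer
#' @param profiles a [plant_profiles()] object.
#' @param k composition size (exactly `k` plants per candidate).
#' @param top_f number of best candidates to retain; when it exceeds
#'   `choose(T, k)` all compositions are returned.
#' @param max_nodes refuse instances with more than this many subsets
#'   (complete search) or abort branch and bound past this many
#'   generated nodes.
#' @return An object of class `formula_candidates`: a data frame with
#'   columns `rank`, `plants`, `k`, `score`, `n_covered`, plus
#'   attributes `sets` (list of plant-id vectors), `covered` (list of
#'   protein-id vectors), `telemetry`
#'   (`nodes_generated`, `nodes_pruned`) and `config`.
#' @export
complete_search <- function(profiles, k, top_f = 10, max_nodes = 1e7) {
  validate_search_args(profiles, k, top_f)
  prep <- bnb_prep(profiles, k)
  n_comb <- choose(prep$T, k)
  if (n_comb > max_nodes) {
    stopf("choose(%d, %d) = %.0f exceeds max_nodes = %.0f",
          prep$T, k, n_comb, max_nodes)
  }
  q <- topf_new(top_f)
  # enumerate k-subsets in lexicographic rank order; the last level is
  # scored column-wise in one vectorised sweep
  recurse <- function(start, depth, vec, chosen) {
    if (depth == k) {
      js <- start:prep$T
      if (k == 1) {
        scores <- prep$totals[js]
      } else {
        M <- pmax(prep$ER[, js, drop = FALSE], vec)
        scores <- as.numeric(crossprod(M, prep$pw))
      }
      worst <- topf_worst(q)
      cand <- which(scores > worst | rep(length(q$scores) < top_f,
                                         length(scores)))
      for (i in cand) {
        topf_insert(q, scores[i], c(chosen, js[i]))
      }
      return(invisible(NULL))
    }
    for (j in start:(prep$T - (k - depth))) {
      recurse(j + 1L, depth + 1L, pmax(vec, prep$ER[, j]), c(chosen, j))
    }
    invisible(NULL)
  }
  recurse(1L, 1L, numeric(nrow(prep$ER)), integer(0))
  assemble_candidates(
    profiles, prep, q,
    telemetry = list(nodes_generated = n_comb, nodes_pruned = 0),
    config = list(k = k, top_f = top_f, strategy = "complete",
                  branching = "wide")
  )
}

# ---- branch and bound ------------------------------------------------

#' @rdname optimizer
#' @param strategy node-expansion order: `"brfs"` (breadth-first, FIFO
#'   queue), `"dfs"` (depth-first, stack, include-branch explored
#'   first) or `"bfs"` (best-first, priority queue).
#' @param branching `"binary"` (children = include / exclude the next
#'   sorted plant) or `"wide"` (one child per remaining plant index;
#'   only supported with `strategy = "brfs"`).
#' @param dominance drop dominated plants first (see
#'   [dominance_filter()]); preserves the top-1 optimum but may alter
#'   lower-ranked candidates, hence off by default.
#' @param bfs_key priority key for best-first search: the node `"bound"`
#'   (default) or its current `"profit"`.
#' @export
branch_and_bound <- function(profiles, k, top_f = 10,
                             strategy = c("brfs", "dfs", "bfs"),
                             branching = c("binary", "wide"),
                             dominance = FALSE,
                             bfs_key = c("bound", "profit"),
                             max_nodes = 1e7) {
  strategy <- match.arg(strategy)
  branching <- match.arg(branching)
  bfs_key <- match.arg(bfs_key)
  if (branching == "wide" && strategy != "brfs") {
    stopf("wide branching is only supported with the brfs strategy")
  }
  if (dominance) profiles <- dominance_filter(profiles, k = k)
  validate_search_args(profiles, k, top_f)
  prep <- bnb_prep(profiles, k)
  q <- topf_new(top_f)
  gen <- 0L
  pruned <- 0L
  seqno <- 0L

  cont <- switch(strategy, brfs = fifo_new(), dfs = stack_new(),
                 bfs = heap_new())
  push <- function(node) {
    seqno <<- seqno + 1L
    switch(strategy,
           brfs = fifo_push(cont, node),
           dfs = stack_push(cont, node),
           bfs = heap_push(cont, node[[bfs_key]], seqno, node))
    invisible(NULL)
  }
  pop <- function() {
    switch(strategy,
           brfs = fifo_pop(cont),
           dfs = stack_pop(cont),
           bfs = heap_pop(cont))
  }
  empty <- function() {
    switch(strategy,
           brfs = cont$head > cont$tail,
           dfs = cont$top == 0L,
           bfs = cont$n == 0L)
  }

  # a child is kept only while its bound beats the F-th best score
  consider <- function(node) {
    if (node$bound > topf_worst(q)) push(node) else pruned <<- pruned + 1L
    invisible(NULL)
  }
  make_candidate <- function(chosen, profit) {
    topf_insert(q, profit, chosen)
    invisible(NULL)
  }
  child_node <- function(chosen, level, vec, profit, w) {
    list(chosen = chosen, level = level, vec = vec, profit = profit,
         w = w, bound = profit + next_totals_sum(prep, level, k - w))
  }

  root <- list(chosen = integer(0), level = 0L,
               vec = numeric(nrow(prep$ER)), profit = 0, w = 0L,
               bound = next_totals_sum(prep, 0L, k))
  push(root)

  while (!empty()) {
    node <- pop()
    if (node$bound <= topf_worst(q)) {
      # bound was valid at enqueue time but the incumbent improved
      pruned <- pruned + 1L
      next
    }
    if (branching == "binary") {
      nxt <- node$level + 1L
      # include child
      vec2 <- pmax(node$vec, prep$ER[, nxt])
      profit2 <- sum(prep$pw * vec2)
      gen <- gen + 1L
      if (node$w + 1L == k) {
        make_candidate(c(node$chosen, nxt), profit2)
      } else if (prep$T - nxt >= k - node$w - 1L) {
        consider(child_node(c(node$chosen, nxt), nxt, vec2, profit2,
                            node$w + 1L))
      } else {
        pruned <- pruned + 1L
      }
      # exclude child
      gen <- gen + 1L
      if (prep$T - nxt >= k - node$w) {
        consider(child_node(node$chosen, nxt, node$vec, node$profit, node$w))
      } else {
        pruned <- pruned + 1L
      }
    } else {
      last <- node$level
      for (j in seq.int(last + 1L, prep$T - (k - node$w - 1L))) {
        vec2 <- pmax(node$vec, prep$ER[, j])
        profit2 <- sum(prep$pw * vec2)
        gen <- gen + 1L
        if (node$w + 1L == k) {
          make_candidate(c(node$chosen, j), profit2)
        } else {
          consider(child_node(c(node$chosen, j), j, vec2, profit2,
                              node$w + 1L))
        }
      }
    }
    if (gen > max_nodes) {
      stopf("branch and bound exceeded max_nodes = %.0f", max_nodes)
    }
  }

  assemble_candidates(
    profiles, prep, q,
    telemetry = list(nodes_generated = gen, nodes_pruned = pruned),
    config = list(k = k, top_f = top_f, strategy = strategy,
                  branching = branching, dominance = dominance,
                  bfs_key = bfs_key)
  )
}

#' Unified search front-end
#'
#' Dispatches to [complete_search()] or [branch_and_bound()] based on
#' a [search_config()].
#'
#' @param profiles a [plant_profiles()] object.
#' @param config a [search_config()].
#' @return A `formula_candidates` object.
#' @export
search_formulas <- function(profiles, config) {
  stopifnot(inherits(config, "search_config"))
  if (config$strategy == "complete") {
    prof <- if (isTRUE(config$dominance)) {
      dominance_filter(profiles, k = config$k)
    } else {
      profiles
    }
    complete_search(prof, config$k, config$top_f,
                    max_nodes = config$max_nodes)
  } else {
    branch_and_bound(profiles, config$k, config$top_f,
                     strategy = config$strategy,
                     branching = config$branching,
                     dominance = config$dominance,
                     bfs_key = config$bfs_key,
                     max_nodes = config$max_nodes)
  }
}

#' Search configuration
#'
#' @param k composition size (exact number of plants per candidate).
#' @param top_f number of candidates retained.
#' @param strategy `"brfs"`, `"dfs"`, `"bfs"` or `"complete"`.
#' @param branching `"binary"` or `"wide"` (wide only with brfs or
#'   complete).
#' @param dominance apply [dominance_filter()] before searching.
#' @param bfs_key best-first priority key, `"bound"` or `"profit"`.
#' @param max_nodes combinatorial guard / node budget.
#' @return Object of class `search_config`.
#' @export
search_config <- function(k, top_f = 10,
                          strategy = c("brfs", "dfs", "bfs", "complete"),
                          branching = c("binary", "wide"),
                          dominance = FALSE,
                          bfs_key = c("bound", "profit"),
                          max_nodes = 1e7) {
  strategy <- match.arg(strategy)
  branching <- match.arg(branching)
  bfs_key <- match.arg(bfs_key)
  if (k < 1 || k != round(k)) stopf("k must be a positive integer")
  if (top_f < 1) stopf("top_f must be a positive integer")
  if (branching == "wide" && !strategy %in% c("brfs", "complete")) {
    stopf("wide branching is only supported with brfs or complete")
  }
  structure(list(k = as.integer(k), top_f = as.integer(top_f),
                 strategy = strategy, branching = branching,
                 dominance = dominance, bfs_key = bfs_key,
                 max_nodes = max_nodes),
            class = "search_config")
}

#' Remove dominated plants
#'
#' Plant X is dominated by plant Y when every protein X can trace is
#' also traced by Y with at least X's edge weight.  Dropping dominated
#' plants cannot lower the best attainable k-subset score.  Among
#' plants with identical profiles the lexicographically smallest id is
#' kept.  If fewer than `k` plants would remain, filtering is skipped
#' with a warning.
#'
#' @param profiles a [plant_profiles()] object.
#' @param k composition size the filtered set must still support.
#' @return A reduced `plant_profiles` object.
#' @export
dominance_filter <- function(profiles, k = 1) {
  stopifnot(inherits(profiles, "plant_profiles"))
  E <- profiles$E
  plants <- profiles$plants
  n <- length(plants)
  removed <- logical(n)
  for (x in seq_len(n)) {
    for (y in seq_len(n)) {
      if (x == y || removed[y]) next
      if (all(E[, x] <= E[, y])) {
        if (all(E[, x] == E[, y]) && plants[y] > plants[x]) next
        removed[x] <- TRUE
        break
      }
    }
  }
  if (sum(!removed) < k) {
    warnf("dominance filter would leave fewer than k plants; skipped")
    return(profiles)
  }
  keep <- plants[!removed]
  plant_profiles(profiles$table[profiles$table$plant_id %in% keep, ,
                                drop = FALSE])
}

#' @export
print.formula_candidates <- function(x, ...) {
  cfg <- attr(x, "config")
  tel <- attr(x, "telemetry")
  cat(sprintf("formula_candidates: top %d compositions of %d plants (%s/%s)\n",
              nrow(x), cfg$k, cfg$strategy,
              cfg$branching %||% "binary"))
  df <- as.data.frame(x)
  df$score <- round_half_up(df$score, 5)
  print.data.frame(df, row.names = FALSE, ...)
  cat(sprintf("nodes generated: %d, pruned: %d\n",
              as.integer(tel$nodes_generated), as.integer(tel$nodes_pruned)))
  invisible(x)
}
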