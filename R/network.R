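#' Plant-compound-protein network container
#'
#' A `tripartite_network` stores plants, compounds and proteins together
#' with undirected weighted edges between them, using an adjacency
#' representation so that enumerating a node's neighbours touches only
#' that node's list.  Three such networks are built in a typical run
#' (the plant-compound-protein network, its similarity-expanded
#' extension, and the disease protein-compound network) and then joined
#' by similarity and protein-identity links before traversal.
#'
#' Node identity is `(kind, id)` with the id canonicalised (trimmed,
#' whitespace-collapsed, case-folded) before comparison: compounds are
#' keyed by CID string, proteins by GI string, plants by Latin name.
#'
#' @param edges optional edge data frame (see [add_edges()]) used to
#'   populate the network.
#' @param network label attached to nodes created from `edges`
#'   (conventionally `"A"`, `"B"` or `"C"`).
#' @return An object of class `tripartite_network`.
#' @examples
#' net <- tripartite_network(data.frame(
#'   source_kind = "plant", source_id = "Mangifera indica",
#'   target_kind = "compound", target_id = "73399",
#'   weight = 1, origin = "plant_compound"))
#' net
#' @export
tripartite_network <- function(edges = NULL, network = "A") {
  net <- structure(
    list(
      nodes = data.frame(key = character(), kind = character(),
                         id = character(), network = character(),
                         stringsAsFactors = FALSE),
      edges = data.frame(from_key = character(), to_key = character(),
                         weight = numeric(), origin = character(),
                         stringsAsFactors = FALSE)
    ),
    class = "tripartite_network"
  )
  if (!is.null(edges)) net <- add_edges(net, edges, network = network)
  net
}

.edge_origins <- c("plant_compound", "compound_protein",
                   "compound_similarity", "protein_identity")
.node_kinds <- c("plant", "compound", "protein")

#' Add edges to a tripartite network
#'
#' Endpoints are created on demand.  Adding the same
#' (source, target, origin) edge twice keeps the larger weight, so the
#' operation is idempotent and consistent with the keep-max update rule
#' used throughout traversal.  Edges are stored undirected: each edge
#' appears in both endpoints' adjacency lists with identical weight and
#' origin.
#'
#' @param net a [tripartite_network()].
#' @param edges data frame with columns `source_kind`, `source_id`,
#'   `target_kind`, `target_id`, `weight`, `origin`.  Weights must lie
#'   in `[0, 1]`; `plant_compound` and `protein_identity` edges must
#'   have weight exactly 1.
#' @param network label for nodes created by this call.
#' @return The updated network.
#' @export
add_edges <- function(net, edges, network = "A") {
  stopifnot(inherits(net, "tripartite_network"))
  req <- c("source_kind", "source_id", "target_kind", "target_id",
           "weight", "origin")
  miss <- setdiff(req, names(edges))
  if (length(miss) > 0) {
    stopf("edge table is missing column(s): %s", paste(miss, collapse = ", "))
  }
  if (nrow(edges) == 0) return(net)
  w <- as.numeric(edges$weight)
  bad <- which(!is.finite(w) | w < 0 | w > 1)
  if (length(bad) > 0) {
    stopf("edge weight outside [0, 1] at row(s): %s",
          paste(utils::head(bad, 5), collapse = ", "))
  }
  if (!all(edges$origin %in% .edge_origins)) {
    stopf("unknown edge origin: %s",
          paste(unique(setdiff(edges$origin, .edge_origins)), collapse = ", "))
  }
  if (!all(edges$source_kind %in% .node_kinds) ||
      !all(edges$target_kind %in% .node_kinds)) {
    stopf("node kind must be one of: %s", paste(.node_kinds, collapse = ", "))
  }
  unit <- edges$origin %in% c("plant_compound", "protein_identity")
  if (any(unit & w != 1)) {
    stopf("%s edges must have weight 1",
          paste(unique(edges$origin[unit & w != 1]), collapse = ", "))
  }

  from <- node_key(edges$source_kind, edges$source_id)
  to <- node_key(edges$target_kind, edges$target_id)
  if (any(from == to)) stopf("self-loop edges are not allowed")

  src_net <- as.character(edges$source_network %||% rep(network, nrow(edges)))
  tgt_net <- as.character(edges$target_network %||% rep(network, nrow(edges)))
  new_nodes <- data.frame(
    key = c(from, to),
    kind = c(edges$source_kind, edges$target_kind),
    id = trimws(c(as.character(edges$source_id), as.character(edges$target_id))),
    network = c(src_net, tgt_net),
    stringsAsFactors = FALSE
  )
  nodes <- rbind(net$nodes, new_nodes)
  nodes <- nodes[!duplicated(nodes$key), , drop = FALSE]

  dir_edges <- data.frame(
    from_key = c(from, to), to_key = c(to, from),
    weight = c(w, w), origin = c(edges$origin, edges$origin),
    stringsAsFactors = FALSE
  )
  all_edges <- rbind(net$edges, dir_edges)
  key <- paste(all_edges$from_key, all_edges$to_key, all_edges$origin,
               sep = "\r")
  best <- tapply(all_edges$weight, key, max)
  first <- !duplicated(key)
  kept <- all_edges[first, , drop = FALSE]
  kept$weight <- as.numeric(best[key[first]])
  rownames(kept) <- NULL
  rownames(nodes) <- NULL
  net$nodes <- nodes
  net$edges <- kept
  net
}

#' @rdname add_edges
#' @param source_kind,source_id,target_kind,target_id endpoint kind and
#'   identifier of a single edge.
#' @param weight edge weight in `[0, 1]`.
#' @param origin one of `"plant_compound"`, `"compound_protein"`,
#'   `"compound_similarity"`, `"protein_identity"`.
#' @export
add_edge <- function(net, source_kind, source_id, target_kind, target_id,
                     weight, origin, network = "A") {
  add_edges(net, data.frame(
    source_kind = source_kind, source_id = source_id,
    target_kind = target_kind, target_id = target_id,
    weight = weight, origin = origin, stringsAsFactors = FALSE
  ), network = network)
}

#' Neighbours of a node
#'
#' @param net a [tripartite_network()].
#' @param kind,id node kind and identifier.
#' @return Data frame with one row per incident edge: neighbour `key`,
#'   `kind`, `id`, and the edge's `weight` and `origin`.
#' @export
node_neighbors <- function(net, kind, id) {
  stopifnot(inherits(net, "tripartite_network"))
  k <- node_key(kind, id)
  hits <- net$edges[net$edges$from_key == k, , drop = FALSE]
  idx <- match(hits$to_key, net$nodes$key)
  data.frame(key = hits$to_key,
             kind = net$nodes$kind[idx], id = net$nodes$id[idx],
             weight = hits$weight, origin = hits$origin,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' @keywords internal
#' @noRd
node_degree <- function(net, kind, id) {
  length(unique(net$edges$to_key[net$edges$from_key == node_key(kind, id)]))
}

# Named list: node key -> integer indices into net$edges (outgoing rows).
#' @keywords internal
#' @noRd
adjacency_index <- function(net) {
  split(seq_len(nrow(net$edges)), net$edges$from_key)
}

#' Link identical proteins between two networks
#'
#' Creates one `protein_identity` edge (weight 1) for every protein
#' identifier present in both networks, after canonicalisation.
#' Identifiers must already be in a shared scheme (GI numbers);
#' cross-database identifier conversion is out of scope.
#'
#' @param net_x,net_y two [tripartite_network()] objects.
#' @return Edge data frame (possibly empty) suitable for [add_edges()].
#' @export
link_protein_identity <- function(net_x, net_y) {
  px <- net_x$nodes[net_x$nodes$kind == "protein", , drop = FALSE]
  py <- net_y$nodes[net_y$nodes$kind == "protein", , drop = FALSE]
  shared <- intersect(px$key, py$key)
  ids <- px$id[match(shared, px$key)]
  data.frame(
    source_kind = rep("protein", length(shared)), source_id = ids,
    target_kind = rep("protein", length(shared)), target_id = ids,
    weight = rep(1, length(shared)),
    origin = rep("protein_identity", length(shared)),
    stringsAsFactors = FALSE
  )
}

#' Merge networks and cross-links into one linked network
#'
#' @param ... any mix of [tripartite_network()] objects and edge data
#'   frames (cross-link tables from [link_protein_identity()],
#'   [threshold_links()] or [best_match_links()]).  Protein-identity
#'   self-pair rows (identical canonical endpoints) are dropped, since
#'   the merged network holds a single node per identifier.
#' @return A single `tripartite_network` containing all nodes and edges,
#'   duplicate edges resolved keep-max.
#' @export
merge_networks <- function(...) {
  parts <- list(...)
  out <- tripartite_network()
  for (p in parts) {
    if (inherits(p, "tripartite_network")) {
      out$nodes <- rbind(out$nodes, p$nodes)
      out$edges <- rbind(out$edges, p$edges)
    } else if (is.data.frame(p)) {
      if (nrow(p) == 0) next
      keep <- !(p$origin == "protein_identity" &
                node_key(p$source_kind, p$source_id) ==
                node_key(p$target_kind, p$target_id))
      out <- add_edges(out, p[keep, , drop = FALSE], network = "X")
    } else {
      stopf("merge_networks() accepts networks and edge data frames")
    }
  }
  out$nodes <- out$nodes[!duplicated(out$nodes$key), , drop = FALSE]
  key <- paste(out$edges$from_key, out$edges$to_key, out$edges$origin,
               sep = "\r")
  best <- tapply(out$edges$weight, key, max)
  first <- !duplicated(key)
  out$edges <- out$edges[first, , drop = FALSE]
  out$edges$weight <- as.numeric(best[key[first]])
  rownames(out$nodes) <- rownames(out$edges) <- NULL
  out
}

#' Remove components unreachable from disease proteins
#'
#' Keeps exactly the nodes reachable (over any edge type) from at least
#' one seed protein, so later traversal works on the smallest
#' equivalent network.  Idempotent.
#'
#' @param net a [tripartite_network()].
#' @param seeds character vector of seed protein identifiers.
#' @return The pruned network.  An empty seed set yields an empty
#'   network, with a warning.
#' @export
prune_untraceable <- function(net, seeds) {
  stopifnot(inherits(net, "tripartite_network"))
  seeds <- unique(as.character(seeds))
  seed_keys <- intersect(node_key("protein", seeds), net$nodes$key)
  if (length(seed_keys) == 0) {
    warnf("no seed protein present in the network; returning empty network")
    return(tripartite_network())
  }
  adj <- adjacency_index(net)
  seen <- new.env(parent = emptyenv())
  for (k in seed_keys) assign(k, TRUE, envir = seen)
  frontier <- seed_keys
  while (length(frontier) > 0) {
    nxt <- unique(net$edges$to_key[unlist(adj[frontier], use.names = FALSE)])
    nxt <- nxt[!vapply(nxt, exists, logical(1), envir = seen)]
    for (k in nxt) assign(k, TRUE, envir = seen)
    frontier <- nxt
  }
  keep <- ls(seen)
  net$nodes <- net$nodes[net$nodes$key %in% keep, , drop = FALSE]
  net$edges <- net$edges[net$edges$from_key %in% keep &
                         net$edges$to_key %in% keep, , drop = FALSE]
  rownames(net$nodes) <- rownames(net$edges) <- NULL
  net
}

#' @export
print.tripartite_network <- function(x, ...) {
  kinds <- table(factor(x$nodes$kind, levels = .node_kinds))
  cat("tripartite_network:",
      sum(kinds), "nodes (", paste(kinds, names(kinds), collapse = ", "),
      "),", nrow(x$edges) / 2, "undirected edges\n")
  if (nrow(x$edges) > 0) {
    org <- table(x$edges$origin) / 2
    cat("  edges by origin:",
        paste(sprintf("%s=%d", names(org), as.integer(org)), collapse = ", "),
        "\n")
  }
  invisible(x)
}

#' @export
summary.tripartite_network <- function(object, ...) {
  print(object, ...)
  invisible(object)
}
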