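#' Trace disease proteins to compounds through the linked networks
#'
#' For every seed protein, finds all compounds from which that protein
#' can be traced and the best edge weight of any route.  A route
#' leaves the seed protein (proteins with the same identifier across
#' networks are one node, i.e. identity links are implicit), crosses
#' exactly one compound-protein interaction edge (contributing 1.0),
#' and may then hop along compound-similarity edges, each hop
#' multiplying in its similarity score.  Per compound and protein the
#' maximum weight over all routes is kept, so a compound with both a
#' direct interaction and a similarity-mediated route records 1.0.
#' In the published networks at the 0.9 similarity cut, routes cross at
#' most one similarity edge, so weights are either 1.0 (direct) or a
#' single similarity score; the multiplicative rule is the conservative
#' generalisation.
#'
#' @param net a linked, typically pruned, [tripartite_network()].
#' @param weights a [normalize_weights()] table for the seed proteins;
#'   its `protein_id` column (or `gene` if absent) names the protein
#'   nodes.
#' @return Object of class `compound_annotations`: a data frame with
#'   one row per traced (compound, protein) pair and columns
#'   `compound_id`, `protein_id`, `gene`, `protein_weight`,
#'   `edge_weight`.  Seeds absent from the network are skipped with a
#'   warning; unreachable compounds are absent.
#' @export
annotate_compounds <- function(net, weights) {
  stopifnot(inherits(net, "tripartite_network"))
  if (!inherits(weights, "protein_weights")) weights <- normalize_weights(weights)
  pid <- if (!is.null(weights$protein_id)) weights$protein_id else weights$gene
  seed_keys <- node_key("protein", pid)
  present <- seed_keys %in% net$nodes$key
  if (any(!present)) {
    warnf("seed protein(s) absent from the network, skipped: %s",
          paste(pid[!present], collapse = ", "))
  }
  adj <- adjacency_index(net)
  node_kind <- net$nodes$kind[match(names(adj), net$nodes$key)]

  rows <- vector("list", sum(present))
  ri <- 0L
  for (s in which(present)) {
    skey <- seed_keys[s]
    # direct interactions: one compound_protein hop, weight 1
    out <- net$edges[adj[[skey]], , drop = FALSE]
    direct <- out$to_key[out$origin == "compound_protein"]
    if (length(direct) == 0) next
    w <- structure(rep(1, length(direct)), names = direct)
    settled <- character(0)
    # widest-path (max-product) propagation along similarity edges
    while (length(w) > length(settled)) {
      open <- setdiff(names(w), settled)
      u <- open[which.max(w[open])]
      settled <- c(settled, u)
      rel <- net$edges[adj[[u]], , drop = FALSE]
      rel <- rel[rel$origin == "compound_similarity", , drop = FALSE]
      if (nrow(rel) == 0) next
      nw <- unname(w[u]) * rel$weight
      for (j in seq_len(nrow(rel))) {
        v <- rel$to_key[j]
        if (nw[j] > 0 && (!(v %in% names(w)) || nw[j] > w[v])) w[v] <- nw[j]
      }
    }
    idx <- match(names(w), net$nodes$key)
    ri <- ri + 1L
    rows[[ri]] <- data.frame(
      compound_key = names(w),
      compound_id = net$nodes$id[idx],
      protein_id = rep(pid[s], length(w)),
      gene = rep(weights$gene[s], length(w)),
      protein_weight = rep(weights$norm[s], length(w)),
      edge_weight = unname(w),
      stringsAsFactors = FALSE
    )
  }
  rows <- rows[seq_len(ri)]
  out <- if (length(rows) == 0) {
    data.frame(compound_key = character(), compound_id = character(),
               protein_id = character(), gene = character(),
               protein_weight = numeric(), edge_weight = numeric(),
               stringsAsFactors = FALSE)
  } else {
    do.call(rbind, rows)
  }
  rownames(out) <- NULL
  class(out) <- c("compound_annotations", "data.frame")
  out
}

#' Stored record for one annotated compound
#'
#' Returns the traversal bookkeeping for a compound in the classic
#' form: a map from traced protein id to
#' `(gene, protein_weight, edge_weight)` plus the traced-protein set
#' (kept as a set to prevent double counting).
#'
#' @param annotations result of [annotate_compounds()].
#' @param compound_id the compound to look up.
#' @return `list(map = <named list>, traced = <character>)`.
#' @export
annotation_record <- function(annotations, compound_id) {
  hit <- annotations[canonical_id(annotations$compound_id) ==
                     canonical_id(compound_id), , drop = FALSE]
  map <- lapply(seq_len(nrow(hit)), function(i) {
    list(gene = hit$gene[i], protein_weight = hit$protein_weight[i],
         edge_weight = hit$edge_weight[i])
  })
  names(map) <- hit$protein_id
  list(map = map, traced = unique(hit$protein_id))
}

#' Backtrack compound annotations to plants
#'
#' Builds the weighted plant-protein bipartite graph: each plant
#' inherits every protein traced from any of its compounds, at the
#' maximum edge weight over those compounds (strictly-greater updates,
#' so adding evidence never lowers a weight).  Plants tracing no
#' protein are omitted.
#'
#' @param annotations result of [annotate_compounds()].
#' @param net the same network the annotations were computed on.
#' @return A [plant_profiles()] object.
#' @export
backtrack_to_plants <- function(annotations, net) {
  stopifnot(inherits(annotations, "compound_annotations"),
            inherits(net, "tripartite_network"))
  pc <- net$edges[net$edges$origin == "plant_compound", , drop = FALSE]
  kind_from <- net$nodes$kind[match(pc$from_key, net$nodes$key)]
  pc <- pc[kind_from == "plant", , drop = FALSE]
  if (nrow(pc) == 0 || nrow(annotations) == 0) {
    return(plant_profiles(data.frame(
      plant_id = character(), protein_id = character(), gene = character(),
      protein_weight = numeric(), edge_weight = numeric(),
      stringsAsFactors = FALSE)))
  }
  plant_id <- net$nodes$id[match(pc$from_key, net$nodes$key)]
  joined <- merge(
    data.frame(plant_id = plant_id, compound_key = pc$to_key,
               stringsAsFactors = FALSE),
    annotations, by = "compound_key"
  )
  if (nrow(joined) == 0) {
    return(plant_profiles(data.frame(
      plant_id = character(), protein_id = character(), gene = character(),
      protein_weight = numeric(), edge_weight = numeric(),
      stringsAsFactors = FALSE)))
  }
  grp <- paste(joined$plant_id, joined$protein_id, sep = "\r")
  best <- tapply(joined$edge_weight, grp, max)
  first <- !duplicated(grp)
  prof <- joined[first, c("plant_id", "protein_id", "gene",
                          "protein_weight"), drop = FALSE]
  prof$edge_weight <- as.numeric(best[grp[first]])
  rownames(prof) <- NULL
  plant_profiles(prof)
}
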