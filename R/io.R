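#' Read and write network edge lists
#'
#' Edge lists are UTF-8 tab-separated files with a header row and
#' columns `source_kind`, `source_id`, `target_kind`, `target_id`,
#' `weight`, `origin` — one file per network plus one for cross-links.
#' Malformed rows are rejected with line numbers.
#'
#' @param path file path.
#' @return `read_edges`: a validated edge data frame.
#' @export
read_edges <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = "character")
  req <- c("source_kind", "source_id", "target_kind", "target_id",
           "weight", "origin")
  miss <- setdiff(req, names(tab))
  if (length(miss) > 0) {
    stopf("%s: missing column(s): %s", path, paste(miss, collapse = ", "))
  }
  w <- suppressWarnings(as.numeric(tab$weight))
  bad <- which(!is.finite(w))
  if (length(bad) > 0) {
    stopf("%s: non-numeric weight at line(s): %s", path,
          paste(utils::head(bad + 1L, 5), collapse = ", "))
  }
  bad <- which(w < 0 | w > 1)
  if (length(bad) > 0) {
    stopf("%s: weight outside [0, 1] at line(s): %s", path,
          paste(utils::head(bad + 1L, 5), collapse = ", "))
  }
  bad <- which(!tab$origin %in% .edge_origins)
  if (length(bad) > 0) {
    stopf("%s: unknown origin at line(s): %s", path,
          paste(utils::head(bad + 1L, 5), collapse = ", "))
  }
  tab$weight <- w
  tab
}

#' @rdname read_edges
#' @param edges an edge data frame (e.g. from [network_edges()] or a
#'   link builder).
#' @return `write_edges`: `path`, invisibly.
#' @export
write_edges <- function(edges, path) {
  req <- c("source_kind", "source_id", "target_kind", "target_id",
           "weight", "origin")
  utils::write.table(edges[req], path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Undirected edge table of a network
#'
#' One row per undirected edge, in the on-disk edge-list layout.
#'
#' @param net a [tripartite_network()].
#' @return Edge data frame.
#' @export
network_edges <- function(net) {
  stopifnot(inherits(net, "tripartite_network"))
  e <- net$edges[net$edges$from_key < net$edges$to_key, , drop = FALSE]
  fi <- match(e$from_key, net$nodes$key)
  ti <- match(e$to_key, net$nodes$key)
  out <- data.frame(
    source_kind = net$nodes$kind[fi], source_id = net$nodes$id[fi],
    target_kind = net$nodes$kind[ti], target_id = net$nodes$id[ti],
    weight = e$weight, origin = e$origin, stringsAsFactors = FALSE
  )
  out <- out[order(out$source_kind, out$source_id, out$target_kind,
                   out$target_id, out$origin), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read and write fingerprint files
#'
#' The sparse format is tab-separated: a header line `#nbits=<L>`
#' declaring the bit length, then one row per compound,
#' `compound_id<TAB>comma-separated 1-based indices of the 1-bits`
#' (empty second field for an all-zero fingerprint).  Rows whose second
#' field is a dense 0/1 string of length L are also accepted.
#'
#' @param path file path.
#' @return `read_fingerprints`: a [fingerprint_set()].
#' @export
read_fingerprints <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  if (length(lines) == 0 || !grepl("^#nbits=\\d+$", lines[1])) {
    stopf("%s: first line must declare the bit length, e.g. #nbits=4860",
          path)
  }
  nbits <- as.integer(sub("^#nbits=", "", lines[1]))
  body <- lines[-1]
  body <- body[nzchar(body)]
  fps <- lapply(seq_along(body), function(i) {
    parts <- strsplit(body[i], "\t", fixed = TRUE)[[1]]
    if (length(parts) < 1 || length(parts) > 2) {
      stopf("%s: malformed row at line %d", path, i + 1L)
    }
    field <- if (length(parts) == 2) parts[2] else ""
    if (grepl("^[01]+$", field) && nchar(field) == nbits) {
      bits <- as.integer(strsplit(field, "", fixed = TRUE)[[1]])
      fingerprint(parts[1], bits, nbits = nbits)
    } else if (field == "") {
      fingerprint(parts[1], integer(0), nbits = nbits, sparse = TRUE)
    } else if (grepl("^\\d+(,\\d+)*$", field)) {
      on <- as.integer(strsplit(field, ",", fixed = TRUE)[[1]])
      if (any(on < 1 | on > nbits)) {
        stopf("%s: bit index out of range at line %d", path, i + 1L)
      }
      fingerprint(parts[1], on, nbits = nbits, sparse = TRUE)
    } else {
      stopf("%s: malformed bit field at line %d", path, i + 1L)
    }
  })
  fingerprint_set(fps)
}

#' @rdname read_fingerprints
#' @param fps a [fingerprint_set()].
#' @return `write_fingerprints`: `path`, invisibly.
#' @export
write_fingerprints <- function(fps, path) {
  stopifnot(inherits(fps, "fingerprint_set"))
  lines <- c(sprintf("#nbits=%d", fps$nbits),
             vapply(seq_along(fps$ids), function(i) {
               paste0(fps$ids[i], "\t",
                      paste(fps$on[[i]], collapse = ","))
             }, character(1)))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Write the plant-protein bipartite graph
#'
#' One row per profile entry:
#' `plant_id gene protein_id protein_weight edge_weight`.
#'
#' @param profiles a [plant_profiles()] object.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_bipartite <- function(profiles, path) {
  stopifnot(inherits(profiles, "plant_profiles"))
  tab <- profiles$table[c("plant_id", "gene", "protein_id",
                          "protein_weight", "edge_weight")]
  tab <- tab[order(tab$plant_id, tab$gene), , drop = FALSE]
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_bipartite
#' @return `read_bipartite`: a [plant_profiles()] object.
#' @export
read_bipartite <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = c(plant_id = "character",
                                          gene = "character",
                                          protein_id = "character"))
  plant_profiles(tab)
}

#' Write a candidate report
#'
#' Writes the ranked formula candidates as a versioned JSON report
#' (full-precision scores, per-protein best edge weights for each
#' candidate, and search telemetry) and, optionally, a human-readable
#' table of composition size, plant names and formula score rounded to
#' 5 decimals.
#'
#' @param candidates a `formula_candidates` object.
#' @param profiles the [plant_profiles()] the search ran on.
#' @param path output JSON path.
#' @param table_path optional path for the plain-text table.
#' @return `path`, invisibly.
#' @export
write_candidates <- function(candidates, profiles, path,
                             table_path = NULL) {
  stopifnot(inherits(candidates, "formula_candidates"),
            inherits(profiles, "plant_profiles"))
  sets <- attr(candidates, "sets")
  report <- list(
    schema = "herbnet-candidates/1",
    config = attr(candidates, "config"),
    telemetry = attr(candidates, "telemetry"),
    candidates = lapply(seq_along(sets), function(i) {
      idx <- match(sets[[i]], profiles$plants)
      w <- apply(profiles$E[, idx, drop = FALSE], 1, max)
      hit <- which(w > 0)
      list(
        rank = i,
        plants = sets[[i]],
        score = candidates$score[i],
        covered = lapply(hit, function(p) list(
          protein_id = profiles$proteins$protein_id[p],
          gene = profiles$proteins$gene[p],
          protein_weight = profiles$proteins$weight[p],
          edge_weight = unname(w[p])
        ))
      )
    })
  )
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  if (!is.null(table_path)) {
    tab <- data.frame(
      composition = candidates$k,
      latin_names = candidates$plants,
      formula_score = sprintf("%.5f", round_half_up(candidates$score, 5)),
      stringsAsFactors = FALSE
    )
    utils::write.table(tab, table_path, sep = "\t", quote = FALSE,
                       row.names = FALSE, fileEncoding = "UTF-8")
  }
  invisible(path)
}

#' Run the full discovery pipeline
#'
#' Executes link -> prune -> traverse -> weight -> search and writes a
#' JSON candidate report plus a readable top-F table.  Inputs come
#' either from files (edge lists, fingerprint files, a centrality
#' table) or from the synthetic generator.
#'
#' @param config a named list (or path to a JSON file holding one)
#'   with elements:
#'   \describe{
#'     \item{simulate}{optional list of [synthetic_spec()] arguments;
#'       when present, inputs are generated instead of read.}
#'     \item{paths}{otherwise, a list with `edges_a`, `edges_b`,
#'       `edges_c`, `fingerprints_a`, `fingerprints_b`,
#'       `fingerprints_c`, `centralities`.}
#'     \item{search}{list of [search_config()] arguments (at least
#'       `k`).}
#'     \item{similarity_threshold}{A-B linking threshold (default
#'       0.9).}
#'     \item{out_dir}{output directory (created if missing).}
#'   }
#' @param quiet suppress stage-level log messages.
#' @return Invisibly, a list with `profiles`, `candidates`, `weights`
#'   and the paths written.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  if (is.character(config)) config <- jsonlite::read_json(config)
  stopifnot(is.list(config))
  log <- function(stage, fmt, ...) {
    if (!quiet) message(sprintf("[%s] %s", stage, sprintf(fmt, ...)))
  }
  scfg <- do.call(search_config, config$search)

  if (!is.null(config$simulate)) {
    sim <- do.call(synthetic_spec, config$simulate)
    gen <- generate_networks(sim)
    net_a <- gen$net_a; net_b <- gen$net_b; net_c <- gen$net_c
    fp_a <- gen$fp_a; fp_b <- gen$fp_b; fp_c <- gen$fp_c
    centralities <- gen$centralities
    log("simulate", "generated networks (seed %d)", sim$seed)
  } else {
    p <- config$paths
    req <- c("edges_a", "edges_c", "fingerprints_a", "fingerprints_c",
             "centralities")
    miss <- setdiff(req, names(p))
    if (length(miss) > 0) {
      stopf("config$paths is missing: %s", paste(miss, collapse = ", "))
    }
    for (f in unlist(p)) {
      if (!file.exists(f)) stopf("input file not found: %s", f)
    }
    net_a <- tripartite_network(read_edges(p$edges_a), network = "A")
    net_b <- if (!is.null(p$edges_b)) {
      tripartite_network(read_edges(p$edges_b), network = "B")
    } else {
      tripartite_network()
    }
    net_c <- tripartite_network(read_edges(p$edges_c), network = "C")
    fp_a <- read_fingerprints(p$fingerprints_a)
    fp_b <- if (!is.null(p$fingerprints_b)) {
      read_fingerprints(p$fingerprints_b)
    }
    fp_c <- read_fingerprints(p$fingerprints_c)
    centralities <- read_centralities(p$centralities)
    log("load", "read networks and fingerprints")
  }

  thr <- config$similarity_threshold %||% 0.9
  links <- list()
  if (!is.null(fp_b)) {
    links$ab <- threshold_links(fp_b, fp_a, threshold = thr)
    log("link", "A-B threshold links (t = %.2f): %d", thr, nrow(links$ab))
  }
  links$ac <- best_match_links(fp_c, fp_a)
  log("link", "A-C best-match links: %d", nrow(links$ac))

  net <- do.call(merge_networks,
                 c(list(net_a, net_b, net_c), unname(links)))
  log("link", "merged network: %d nodes, %d edges",
      nrow(net$nodes), nrow(net$edges) / 2)

  weights <- normalize_weights(centralities)
  seed_ids <- if (!is.null(weights$protein_id)) {
    weights$protein_id
  } else {
    weights$gene
  }
  net <- prune_untraceable(net, seed_ids)
  log("prune", "traceable subnetwork: %d nodes, %d edges",
      nrow(net$nodes), nrow(net$edges) / 2)

  ann <- annotate_compounds(net, weights)
  log("traverse", "annotated compounds: %d",
      length(unique(ann$compound_id)))
  profiles <- backtrack_to_plants(ann, net)
  log("traverse", "plants with a profile: %d", length(profiles$plants))

  candidates <- search_formulas(profiles, scfg)
  tel <- attr(candidates, "telemetry")
  log("search", "top %d of C(%d, %d); nodes generated %d, pruned %d",
      nrow(candidates), length(profiles$plants), scfg$k,
      as.integer(tel$nodes_generated), as.integer(tel$nodes_pruned))

  paths <- list()
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    paths$report <- file.path(config$out_dir, "candidates.json")
    paths$table <- file.path(config$out_dir, "candidates.tsv")
    paths$bipartite <- file.path(config$out_dir, "bipartite.tsv")
    write_candidates(candidates, profiles, paths$report, paths$table)
    write_bipartite(profiles, paths$bipartite)
    log("write", "report written to %s", paths$report)
  }

  invisible(list(profiles = profiles, candidates = candidates,
                 weights = weights, paths = paths))
}
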