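# Independent traversal oracle: fixpoint relaxation over similarity
# edges (no ordering assumptions), after seeding direct interactions.
annotate_oracle <- function(net, weights) {
  pid <- if (!is.null(weights$protein_id)) weights$protein_id else weights$gene
  sim <- net$edges[net$edges$origin == "compound_similarity", , drop = FALSE]
  out <- list()
  for (s in seq_along(pid)) {
    skey <- node_key("protein", pid[s])
    direct <- net$edges$to_key[net$edges$from_key == skey &
                               net$edges$origin == "compound_protein"]
    if (length(direct) == 0) next
    w <- structure(rep(1, length(direct)), names = direct)
    repeat {
      changed <- FALSE
      for (i in seq_len(nrow(sim))) {
        u <- sim$from_key[i]; v <- sim$to_key[i]
        if (u %in% names(w)) {
          nw <- w[[u]] * sim$weight[i]
          if (nw > 0 && (!(v %in% names(w)) || nw > w[[v]])) {
            w[v] <- nw
            changed <- TRUE
          }
        }
      }
      if (!changed) break
    }
    out[[pid[s]]] <- w
  }
  out
}

akt1_fixture <- function() {
  w <- t2dm_weights()
  w$protein_id <- ""
  w$protein_id[w$gene == "AKT1"] <- "60391226"
  w$protein_id[w$protein_id == ""] <- paste0("gi", seq_len(sum(w$protein_id == "")))
  edges <- data.frame(
    source_kind = c("compound", "compound", "plant"),
    source_id = c("500001", "500001", "Schisandra chinensis Baill."),
    target_kind = c("protein", "compound", "compound"),
    target_id = c("60391226", "73399", "73399"),
    weight = c(1, 0.9, 1),
    origin = c("compound_protein", "compound_similarity", "plant_compound"),
    stringsAsFactors = FALSE
  )
  list(net = tripartite_network(edges), weights = w)
}

test_that("a similarity-only route stores the similarity score", {
  fx <- akt1_fixture()
  expect_warning(ann <- annotate_compounds(fx$net, fx$weights), "absent")
  rec <- annotation_record(ann, "73399")
  expect_equal(rec$traced, "60391226")
  expect_equal(rec$map[["60391226"]]$gene, "AKT1")
  expect_equal(rec$map[["60391226"]]$edge_weight, 0.9)
  # protein weight recomputed from the printed centralities
  expect_equal(rec$map[["60391226"]]$protein_weight, 0.7993787198,
               tolerance = 1e-4)
  # the relay compound has the direct interaction at weight 1
  expect_equal(annotation_record(ann, "500001")$map[["60391226"]]$edge_weight, 1)
})

test_that("a direct route wins over a similarity route", {
  fx <- akt1_fixture()
  net <- add_edge(fx$net, "compound", "73399", "protein", "60391226",
                  1, "compound_protein")
  expect_warning(ann <- annotate_compounds(net, fx$weights), "absent")
  expect_equal(annotation_record(ann, "73399")$map[["60391226"]]$edge_weight, 1)
})

test_that("multi-hop similarity routes multiply their scores", {
  fx <- akt1_fixture()
  net <- add_edge(fx$net, "compound", "73399", "compound", "far",
                  0.95, "compound_similarity")
  expect_warning(ann <- annotate_compounds(net, fx$weights), "absent")
  expect_equal(annotation_record(ann, "far")$map[["60391226"]]$edge_weight,
               0.9 * 0.95)
})

test_that("annotations equal the fixpoint-relaxation oracle on random networks", {
  set.seed(23)
  for (rep in 1:5) {
    n_c <- 30
    cids <- sprintf("c%03d", seq_len(n_c))
    gis <- sprintf("70%02d", 1:4)
    rows <- list()
    for (g in gis) {
      hit <- sample(cids, sample(1:4, 1))
      rows[[length(rows) + 1]] <- data.frame(
        source_kind = "compound", source_id = hit,
        target_kind = "protein", target_id = g,
        weight = 1, origin = "compound_protein", stringsAsFactors = FALSE)
    }
    pairs <- t(combn(cids, 2))
    pick <- sample(nrow(pairs), 40)
    rows[[length(rows) + 1]] <- data.frame(
      source_kind = "compound", source_id = pairs[pick, 1],
      target_kind = "compound", target_id = pairs[pick, 2],
      weight = runif(40, 0.85, 1), origin = "compound_similarity",
      stringsAsFactors = FALSE)
    net <- tripartite_network(do.call(rbind, rows))
    weights <- normalize_weights(data.frame(
      gene = toupper(gis), protein_id = gis,
      bc = runif(4, 0, 0.3), cc = runif(4, 0.3, 0.6)))
    ann <- annotate_compounds(net, weights)
    oracle <- annotate_oracle(net, weights)
    for (g in gis) {
      got <- ann[ann$protein_id == g, , drop = FALSE]
      want <- oracle[[g]]
      expect_setequal(got$compound_key, names(want))
      expect_equal(got$edge_weight[match(names(want), got$compound_key)],
                   unname(want))
    }
  }
})

test_that("backtracking takes the per-protein maximum over a plant's compounds", {
  fx <- akt1_fixture()
  # second compound of the same plant with a direct interaction
  net <- add_edges(fx$net, data.frame(
    source_kind = c("plant", "compound"),
    source_id = c("Schisandra chinensis Baill.", "88888"),
    target_kind = c("compound", "protein"),
    target_id = c("88888", "60391226"),
    weight = 1, origin = c("plant_compound", "compound_protein"),
    stringsAsFactors = FALSE))
  expect_warning(ann <- annotate_compounds(net, fx$weights), "absent")
  prof <- backtrack_to_plants(ann, net)
  tab <- prof$table
  expect_equal(nrow(tab), 1)
  expect_equal(tab$edge_weight, 1)  # max(0.9 via 73399, 1.0 via 88888)

  # with only the similarity compound the profile equals the annotation
  expect_warning(ann0 <- annotate_compounds(fx$net, fx$weights), "absent")
  prof0 <- backtrack_to_plants(ann0, fx$net)
  expect_equal(prof0$table$edge_weight, 0.9)
  expect_equal(prof0$table$plant_id, "Schisandra chinensis Baill.")
})

test_that("profiles equal a brute-force max over plant-compound-protein triples", {
  set.seed(29)
  for (rep in 1:3) {
    cids <- sprintf("c%02d", 1:20)
    plants <- sprintf("pl%02d", 1:6)
    gis <- sprintf("71%02d", 1:3)
    rows <- list(
      data.frame(source_kind = "plant",
                 source_id = rep(plants, each = 4),
                 target_kind = "compound",
                 target_id = sample(cids, 24, replace = TRUE),
                 weight = 1, origin = "plant_compound",
                 stringsAsFactors = FALSE),
      data.frame(source_kind = "compound",
                 source_id = sample(cids, 8),
                 target_kind = "protein",
                 target_id = sample(gis, 8, replace = TRUE),
                 weight = 1, origin = "compound_protein",
                 stringsAsFactors = FALSE)
    )
    pairs <- t(combn(cids, 2))
    pick <- sample(nrow(pairs), 25)
    rows[[3]] <- data.frame(
      source_kind = "compound", source_id = pairs[pick, 1],
      target_kind = "compound", target_id = pairs[pick, 2],
      weight = runif(25, 0.85, 1), origin = "compound_similarity",
      stringsAsFactors = FALSE)
    net <- tripartite_network(do.call(rbind, rows))
    weights <- normalize_weights(data.frame(
      gene = toupper(gis), protein_id = gis,
      bc = runif(3, 0, 0.3), cc = runif(3, 0.3, 0.6)))
    # a protein may draw no interacting compound; its seed is skipped
    ann <- suppressWarnings(annotate_compounds(net, weights))
    prof <- backtrack_to_plants(ann, net)

    # triple-loop oracle over (plant, compound, protein)
    pc <- net$edges[net$edges$origin == "plant_compound", , drop = FALSE]
    pc <- pc[startsWith(pc$from_key, "plant|"), , drop = FALSE]
    for (pl in unique(prof$table$plant_id)) {
      comps <- pc$to_key[pc$from_key == node_key("plant", pl)]
      for (g in gis) {
        hits <- ann$edge_weight[ann$protein_id == g &
                                ann$compound_key %in% comps]
        got <- prof$table$edge_weight[prof$table$plant_id == pl &
                                      prof$table$protein_id == g]
        if (length(hits) == 0) {
          expect_equal(length(got), 0)
        } else {
          expect_equal(got, max(hits))
        }
      }
    }
  }
})

test_that("adding a compound never lowers a plant's profile weights", {
  fx <- akt1_fixture()
  expect_warning(ann <- annotate_compounds(fx$net, fx$weights), "absent")
  before <- backtrack_to_plants(ann, fx$net)$table
  net <- add_edges(fx$net, data.frame(
    source_kind = c("plant", "compound"),
    source_id = c("Schisandra chinensis Baill.", "new"),
    target_kind = c("compound", "protein"),
    target_id = c("new", "60391226"),
    weight = 1, origin = c("plant_compound", "compound_protein"),
    stringsAsFactors = FALSE))
  expect_warning(ann2 <- annotate_compounds(net, fx$weights), "absent")
  after <- backtrack_to_plants(ann2, net)$table
  merged <- merge(before, after, by = c("plant_id", "protein_id"))
  expect_true(all(merged$edge_weight.y >= merged$edge_weight.x))
})

test_that("a plant's total value equals its singleton formula score", {
  set.seed(37)
  prof <- generate_bipartite(n_plants = 10, n_proteins = 8, seed = 41)
  for (pl in prof$plants) {
    expect_equal(plant_total_value(prof, pl),
                 formula_score(prof, pl)$score)
  }
})
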