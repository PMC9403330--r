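#' Specification for synthetic network generation
#'
#' Describes a seeded synthetic instance of the three pharmacological
#' networks so the whole pipeline can run with no database access.
#' Defaults are a desk-scale rendition of the real study's structure:
#' 21 disease proteins (the published count of type II diabetes target
#' genes), sparse 4860-bit fingerprints, a 0.9 similarity regime for
#' near-duplicate compounds, and plants holding a handful of compounds
#' each.
#'
#' @param n_plants number of plants in network A.
#' @param n_compounds number of compounds in network A.
#' @param n_proteins number of disease target proteins.
#' @param compounds_per_plant integer range (length-2) of compounds per
#'   plant.
#' @param proteins_per_compound integer range of direct protein
#'   interactions per compound (0 allowed).
#' @param fingerprint_length fingerprint length in bits.
#' @param bit_density expected fraction of 1-bits per fingerprint.
#' @param similarity_pair_fraction fraction of network A compounds that
#'   get a near-duplicate in network B.
#' @param similarity_noise fraction of extra bits switched on in a
#'   near-duplicate; 0 gives identical fingerprints, the default 0.1
#'   keeps the pair's Tanimoto similarity at or above 0.9.
#' @param direct_prob probability that a simulated bipartite edge is a
#'   direct interaction (weight 1) rather than similarity-mediated
#'   (weight uniform on [0.9, 1)).
#' @param seed integer RNG seed; every generated artefact is fully
#'   reproducible from it.
#' @return Object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_plants = 30, n_compounds = 90, n_proteins = 21,
                           compounds_per_plant = c(1, 5),
                           proteins_per_compound = c(0, 3),
                           fingerprint_length = 4860,
                           bit_density = 0.02,
                           similarity_pair_fraction = 0.3,
                           similarity_noise = 0.1,
                           direct_prob = 0.5,
                           seed = 1) {
  if (n_plants < 1 || n_compounds < 1 || n_proteins < 1) {
    stopf("all counts must be at least 1")
  }
  if (bit_density <= 0 || bit_density >= 1) {
    stopf("bit_density must lie strictly between 0 and 1")
  }
  if (similarity_pair_fraction < 0 || similarity_pair_fraction > 1) {
    stopf("similarity_pair_fraction must lie in [0, 1]")
  }
  if (similarity_noise < 0 || similarity_noise > 1 / 9) {
    stopf("similarity_noise above 1/9 would break the 0.9 similarity regime")
  }
  stopifnot(length(compounds_per_plant) == 2,
            length(proteins_per_compound) == 2)
  structure(
    list(n_plants = as.integer(n_plants),
         n_compounds = as.integer(n_compounds),
         n_proteins = as.integer(n_proteins),
         compounds_per_plant = as.integer(compounds_per_plant),
         proteins_per_compound = as.integer(proteins_per_compound),
         fingerprint_length = as.integer(fingerprint_length),
         bit_density = bit_density,
         similarity_pair_fraction = similarity_pair_fraction,
         similarity_noise = similarity_noise,
         direct_prob = direct_prob,
         seed = as.integer(seed)),
    class = "synthetic_spec"
  )
}

#' @keywords internal
#' @noRd
rand_fingerprint <- function(id, nbits, density) {
  n_on <- max(1L, stats::rbinom(1, nbits, density))
  fingerprint(id, sample.int(nbits, n_on), nbits = nbits, sparse = TRUE)
}

#' @keywords internal
#' @noRd
sample_range <- function(rng) {
  if (rng[1] == rng[2]) rng[1] else sample(seq(rng[1], rng[2]), 1)
}

#' Generate the three synthetic networks
#'
#' Draws network A (plants, compounds with fingerprints, direct
#' compound-protein interactions), network B (near-duplicate compounds
#' of a fraction of A's, with their own protein interactions) and
#' network C (the disease proteins with a centrality table and their
#' interacting compounds, fingerprinted for best-match linking).
#' Every disease protein is given at least one interacting compound in
#' network C so traversal seeds are never isolated.
#'
#' @param spec a [synthetic_spec()].
#' @return List with elements `net_a`, `net_b`, `net_c`
#'   ([tripartite_network()] objects), `fp_a`, `fp_b`, `fp_c`
#'   ([fingerprint_set()] objects; `fp_b` is `NULL` when no duplicate
#'   was drawn), `centralities` (data frame `gene`, `protein_id`,
#'   `bc`, `cc`) and `spec`.
#' @export
generate_networks <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  with_seed(spec$seed, {
    genes <- sprintf("G%02d", seq_len(spec$n_proteins))
    gis <- as.character(60000000L + seq_len(spec$n_proteins))
    centralities <- data.frame(
      gene = genes, protein_id = gis,
      bc = round(stats::runif(spec$n_proteins, 0, 0.35), 4),
      cc = round(stats::runif(spec$n_proteins, 0.30, 0.65), 4),
      stringsAsFactors = FALSE
    )

    plants <- sprintf("Plantus synth%03d", seq_len(spec$n_plants))
    cids_a <- as.character(100000L + seq_len(spec$n_compounds))

    # network A: plant-compound membership + direct interactions
    pc <- do.call(rbind, lapply(seq_len(spec$n_plants), function(i) {
      nc <- sample_range(spec$compounds_per_plant)
      data.frame(source_kind = "plant", source_id = plants[i],
                 target_kind = "compound",
                 target_id = sample(cids_a, min(nc, length(cids_a))),
                 weight = 1, origin = "plant_compound",
                 stringsAsFactors = FALSE)
    }))
    cp_rows <- lapply(cids_a, function(cid) {
      np <- sample_range(spec$proteins_per_compound)
      if (np == 0) return(NULL)
      data.frame(source_kind = "compound", source_id = cid,
                 target_kind = "protein",
                 target_id = sample(gis, min(np, length(gis))),
                 weight = 1, origin = "compound_protein",
                 stringsAsFactors = FALSE)
    })
    cp <- do.call(rbind, cp_rows[!vapply(cp_rows, is.null, logical(1))])
    net_a <- tripartite_network(rbind(pc, cp), network = "A")

    fp_a <- fingerprint_set(lapply(cids_a, rand_fingerprint,
                                   nbits = spec$fingerprint_length,
                                   density = spec$bit_density))

    # network B: near-duplicates of a fraction of A's compounds
    n_dup <- round(spec$similarity_pair_fraction * spec$n_compounds)
    fp_b <- NULL
    net_b <- tripartite_network()
    if (n_dup > 0) {
      dup_of <- sample(seq_along(cids_a), n_dup)
      cids_b <- as.character(900000L + seq_len(n_dup))
      fps_b <- lapply(seq_len(n_dup), function(i) {
        on <- fp_a$on[[dup_of[i]]]
        extra <- floor(spec$similarity_noise * length(on))
        if (extra > 0) {
          off <- setdiff(seq_len(spec$fingerprint_length), on)
          on <- c(on, sample(off, min(extra, length(off))))
        }
        fingerprint(cids_b[i], on, nbits = spec$fingerprint_length,
                    sparse = TRUE)
      })
      fp_b <- fingerprint_set(fps_b)
      bp_rows <- lapply(cids_b, function(cid) {
        np <- max(1L, sample_range(spec$proteins_per_compound))
        data.frame(source_kind = "compound", source_id = cid,
                   target_kind = "protein",
                   target_id = sample(gis, min(np, length(gis))),
                   weight = 1, origin = "compound_protein",
                   stringsAsFactors = FALSE)
      })
      net_b <- tripartite_network(do.call(rbind, bp_rows), network = "B")
    }

    # network C: disease proteins and their interacting compounds;
    # round-robin assignment keeps every protein seeded
    n_cc <- max(spec$n_proteins, ceiling(spec$n_compounds / 3))
    cids_c <- as.character(500000L + seq_len(n_cc))
    cc_rows <- lapply(seq_len(n_cc), function(i) {
      tgt <- unique(c(gis[(i - 1L) %% spec$n_proteins + 1L],
                      sample(gis, sample_range(spec$proteins_per_compound))))
      data.frame(source_kind = "compound", source_id = cids_c[i],
                 target_kind = "protein", target_id = tgt,
                 weight = 1, origin = "compound_protein",
                 stringsAsFactors = FALSE)
    })
    net_c <- tripartite_network(do.call(rbind, cc_rows), network = "C")
    fp_c <- fingerprint_set(lapply(cids_c, rand_fingerprint,
                                   nbits = spec$fingerprint_length,
                                   density = spec$bit_density))

    list(net_a = net_a, net_b = net_b, net_c = net_c,
         fp_a = fp_a, fp_b = fp_b, fp_c = fp_c,
         centralities = centralities, spec = spec)
  })
}

#' Generate a synthetic plant-protein bipartite graph
#'
#' Draws plant protein-profiles directly (skipping network traversal),
#' for exercising the scoring and search modules.  Edge weights follow
#' the two observed regimes: a direct interaction (weight 1) with
#' probability `direct_prob`, otherwise a similarity-mediated weight
#' uniform on [0.9, 1).  Protein weights come from
#' [normalize_weights()] on simulated centralities.
#'
#' With `planted_k`, the first `planted_k` plants are constructed to be
#' the unique optimal composition of that size: each covers its own
#' block of maximum-weight proteins at weight 1, every other plant
#' covers only "light" proteins whose weights sum to less than one
#' block, so any k-set that misses a planted plant forfeits more than
#' it can regain.
#'
#' @param n_plants number of plants.
#' @param n_proteins number of disease proteins.
#' @param proteins_per_plant integer range of proteins per plant.
#' @param direct_prob probability of a weight-1 direct edge.
#' @param planted_k if not `NULL`, plant an optimal composition of this
#'   size (requires enough proteins for `planted_k` disjoint blocks of
#'   `planted_block` plus one light protein).
#' @param planted_block heavy proteins per planted plant.
#' @param seed integer RNG seed.
#' @return A [plant_profiles()] object; when planting, the optimal
#'   plant set is in `attr(, "planted")`.
#' @export
generate_bipartite <- function(n_plants = 30, n_proteins = 21,
                               proteins_per_plant = c(1, 8),
                               direct_prob = 0.5,
                               planted_k = NULL, planted_block = 3,
                               seed = 1) {
  if (n_plants < 1 || n_proteins < 1) stopf("counts must be at least 1")
  with_seed(seed, {
    plants <- sprintf("Plantus synth%03d", seq_len(n_plants))
    genes <- sprintf("G%02d", seq_len(n_proteins))
    gis <- as.character(60000000L + seq_len(n_proteins))

    draw_weight <- function(n) {
      ifelse(stats::runif(n) < direct_prob, 1, stats::runif(n, 0.9, 1))
    }

    if (is.null(planted_k)) {
      pw <- normalize_weights(data.frame(
        gene = genes, protein_id = gis,
        bc = stats::runif(n_proteins, 0, 0.35),
        cc = stats::runif(n_proteins, 0.30, 0.65),
        stringsAsFactors = FALSE
      ))
      rows <- lapply(seq_len(n_plants), function(i) {
        np <- sample_range(pmin(proteins_per_plant, n_proteins))
        idx <- sample(n_proteins, np)
        data.frame(plant_id = plants[i], protein_id = gis[idx],
                   gene = genes[idx], protein_weight = pw$norm[idx],
                   edge_weight = draw_weight(np),
                   stringsAsFactors = FALSE)
      })
      return(plant_profiles(do.call(rbind, rows)))
    }

    k <- as.integer(planted_k)
    m <- as.integer(planted_block)
    n_heavy <- k * m
    if (n_proteins <= n_heavy) {
      stopf("planting k = %d blocks of %d needs more than %d proteins",
            k, m, n_heavy)
    }
    if (n_plants <= k) stopf("planting needs decoy plants (n_plants > k)")
    n_light <- n_proteins - n_heavy
    # heavy proteins share the maximum average, so each normalises to 1;
    # light weights sum to m/2 < one block, making the plant strictly
    # optimal by construction
    light_avg <- 0.5 * m / n_light
    if (light_avg >= 1) {
      stopf("planting needs more light proteins: n_proteins > %d",
            n_heavy + floor(m / 2))
    }
    avg <- c(rep(1, n_heavy), rep(light_avg, n_light))
    cc <- pmin(avg, 0.65)
    pw <- normalize_weights(data.frame(
      gene = genes, protein_id = gis, bc = 2 * avg - cc, cc = cc,
      stringsAsFactors = FALSE
    ))
    planted_rows <- lapply(seq_len(k), function(i) {
      idx <- ((i - 1L) * m + 1L):(i * m)
      data.frame(plant_id = plants[i], protein_id = gis[idx],
                 gene = genes[idx], protein_weight = pw$norm[idx],
                 edge_weight = 1,
                 stringsAsFactors = FALSE)
    })
    light_idx <- (n_heavy + 1L):n_proteins
    decoy_rows <- lapply((k + 1L):n_plants, function(i) {
      np <- sample(seq_len(min(n_light, max(proteins_per_plant))), 1)
      idx <- sample(light_idx, np)
      data.frame(plant_id = plants[i], protein_id = gis[idx],
                 gene = genes[idx], protein_weight = pw$norm[idx],
                 edge_weight = stats::runif(np, 0.9, 1),
                 stringsAsFactors = FALSE)
    })
    out <- plant_profiles(do.call(rbind, c(planted_rows, decoy_rows)))
    attr(out, "planted") <- sort(plants[seq_len(k)])
    out
  })
}
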