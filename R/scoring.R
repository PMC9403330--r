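#' Weighted plant-protein bipartite graph
#'
#' The collection of plant protein-profiles produced by traversal (or
#' simulated directly).  Each profile maps a plant to the disease
#' proteins it can reach, with the best edge weight per protein; the
#' plant's `total_value` is its singleton formula score
#' `sum(protein_weight * edge_weight)`.
#'
#' Internally the profiles are also held as a proteins x plants weight
#' matrix (0 marks an absent edge; present edges lie in (0, 1]) so
#' that scoring a plant set is a column-wise maximum.
#'
#' @param table data frame with columns `plant_id`, `protein_id`,
#'   `gene`, `protein_weight`, `edge_weight` (one row per bipartite
#'   edge).
#' @return Object of class `plant_profiles` with elements `table`,
#'   `plants` (lexicographic), `proteins` (per-protein gene and
#'   weight), `E` (edge-weight matrix) and `totals` (named total
#'   values).
#' @export
plant_profiles <- function(table) {
  req <- c("plant_id", "protein_id", "gene", "protein_weight", "edge_weight")
  miss <- setdiff(req, names(table))
  if (length(miss) > 0) {
    stopf("profile table is missing column(s): %s",
          paste(miss, collapse = ", "))
  }
  if (nrow(table) > 0) {
    if (any(table$edge_weight <= 0 | table$edge_weight > 1)) {
      stopf("profile edge weights must lie in (0, 1]")
    }
    if (any(table$protein_weight < 0)) {
      stopf("protein weights must be non-negative")
    }
    pw <- tapply(table$protein_weight, table$protein_id,
                 function(v) length(unique(v)))
    if (any(pw > 1)) stopf("inconsistent protein_weight for a protein_id")
    if (anyDuplicated(paste(table$plant_id, table$protein_id, sep = "\r"))) {
      stopf("duplicate (plant, protein) rows in profile table")
    }
  }
  plants <- sort(unique(as.character(table$plant_id)))
  pids <- sort(unique(as.character(table$protein_id)))
  proteins <- data.frame(
    protein_id = pids,
    gene = as.character(table$gene[match(pids, table$protein_id)]),
    weight = as.numeric(table$protein_weight[match(pids, table$protein_id)]),
    stringsAsFactors = FALSE
  )
  E <- matrix(0, nrow = length(pids), ncol = length(plants),
              dimnames = list(pids, plants))
  if (nrow(table) > 0) {
    E[cbind(match(table$protein_id, pids), match(table$plant_id, plants))] <-
      table$edge_weight
  }
  totals <- as.numeric(crossprod(E, proteins$weight))
  names(totals) <- plants
  structure(
    list(table = as.data.frame(table, stringsAsFactors = FALSE),
         plants = plants, proteins = proteins, E = E, totals = totals),
    class = "plant_profiles"
  )
}

#' Formula score of a plant set
#'
#' The score of a candidate herbal formula is
#' `sum_i P_i * W_i` over the disease proteins it covers, where `P_i`
#' is the normalised protein weight and `W_i` the best edge weight any
#' member plant has for protein `i`.  Each protein is counted once, at
#' the maximum over member plants, so overlapping coverage is never
#' double-counted; the score is therefore monotone and subadditive in
#' the plant set, which is what makes the additive search bound valid.
#'
#' @param profiles a [plant_profiles()] object.
#' @param plants character vector of member plant ids (the empty set
#'   scores 0).
#' @return `list(score = <numeric>, covered = <character>)`, `covered`
#'   being the protein ids the set can trace.
#' @export
formula_score <- function(profiles, plants) {
  stopifnot(inherits(profiles, "plant_profiles"))
  plants <- unique(as.character(plants))
  if (length(plants) == 0) return(list(score = 0, covered = character(0)))
  idx <- match(plants, profiles$plants)
  if (anyNA(idx)) {
    stopf("unknown plant id(s): %s",
          paste(plants[is.na(idx)], collapse = ", "))
  }
  w <- apply(profiles$E[, idx, drop = FALSE], 1, max)
  list(score = sum(profiles$proteins$weight * w),
       covered = profiles$proteins$protein_id[w > 0])
}

#' @rdname formula_score
#' @param plant a single plant id; `plant_total_value` is the singleton
#'   formula score (the branch-and-bound "profit" of that plant).
#' @export
plant_total_value <- function(profiles, plant) {
  stopifnot(inherits(profiles, "plant_profiles"))
  idx <- match(as.character(plant), profiles$plants)
  if (is.na(idx)) stopf("unknown plant id: %s", plant)
  unname(profiles$totals[idx])
}

#' @export
print.plant_profiles <- function(x, ...) {
  cat(sprintf("plant_profiles: %d plants x %d proteins, %d edges\n",
              length(x$plants), nrow(x$proteins), nrow(x$table)))
  if (length(x$totals) > 0) {
    top <- sort(x$totals, decreasing = TRUE)
    show <- utils::head(top, 5)
    cat("  top total values:",
        paste(sprintf("%s=%.4f", names(show), show), collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
summary.plant_profiles <- function(object, ...) {
  print(object)
  if (nrow(object$proteins) > 0) {
    cat(sprintf("  max attainable formula score: %.4f\n",
                sum(object$proteins$weight)))
  }
  invisible(object)
}
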