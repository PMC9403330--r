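#' Binary molecular fingerprints
#'
#' Compounds are compared through fixed-length binary substructure
#' fingerprints (by default 4860 bits, the Klekota-Roth length).
#' A `fingerprint` stores the compound id and the sorted indices of its
#' 1-bits; a `fingerprint_set` is a collection sharing one bit length.
#'
#' @param compound_id compound identifier (CID string).
#' @param bits either a 0/1 vector of length `nbits`, or (when
#'   `sparse = TRUE`) a vector of 1-based indices of the 1-bits.
#' @param nbits fingerprint length in bits.
#' @param sparse whether `bits` holds indices rather than a dense 0/1
#'   vector.
#' @return An object of class `fingerprint` with elements
#'   `compound_id`, `nbits`, `on` (sorted integer indices) and
#'   `popcount`.
#' @examples
#' fp <- fingerprint("73399", c(1, 7, 12), nbits = 4860, sparse = TRUE)
#' fp$popcount
#' @export
fingerprint <- function(compound_id, bits, nbits = 4860L, sparse = FALSE) {
  if (sparse) {
    on <- sort(unique(as.integer(bits)))
    if (length(on) > 0 && (min(on) < 1 || max(on) > nbits)) {
      stopf("fingerprint bit index outside 1..%d for compound %s",
            nbits, compound_id)
    }
  } else {
    bits <- as.integer(bits)
    if (length(bits) != nbits) {
      stopf("fingerprint for %s has %d bits, expected %d",
            compound_id, length(bits), nbits)
    }
    if (!all(bits %in% c(0L, 1L))) {
      stopf("fingerprint for %s contains values other than 0/1", compound_id)
    }
    on <- which(bits == 1L)
  }
  structure(
    list(compound_id = as.character(compound_id), nbits = as.integer(nbits),
         on = on, popcount = length(on)),
    class = "fingerprint"
  )
}

#' @rdname fingerprint
#' @param fps list of `fingerprint` objects with a common bit length.
#' @export
fingerprint_set <- function(fps) {
  if (inherits(fps, "fingerprint")) fps <- list(fps)
  stopifnot(all(vapply(fps, inherits, logical(1), "fingerprint")))
  if (length(fps) == 0) stopf("empty fingerprint set")
  nb <- unique(vapply(fps, `[[`, integer(1), "nbits"))
  if (length(nb) != 1) stopf("fingerprints have mixed bit lengths")
  ids <- vapply(fps, `[[`, character(1), "compound_id")
  if (anyDuplicated(ids)) stopf("duplicate compound ids in fingerprint set")
  structure(list(ids = ids, nbits = nb,
                 on = lapply(fps, `[[`, "on")),
            class = "fingerprint_set")
}

#' Tanimoto coefficient of two fingerprints
#'
#' The Tanimoto (Jaccard) similarity `c / (a + b - c)` where `a` and
#' `b` are the two popcounts and `c` the number of shared 1-bits.  It
#' approaches 1 for structurally similar compounds and 0 for dissimilar
#' ones.  Two all-zero fingerprints give 0 (no structural evidence of
#' similarity), with a warning.
#'
#' @param fa,fb [fingerprint()] objects of equal bit length.
#' @return Similarity in `[0, 1]`.
#' @export
tanimoto <- function(fa, fb) {
  stopifnot(inherits(fa, "fingerprint"), inherits(fb, "fingerprint"))
  if (fa$nbits != fb$nbits) {
    stopf("fingerprint length mismatch: %d vs %d", fa$nbits, fb$nbits)
  }
  a <- fa$popcount
  b <- fb$popcount
  if (a == 0 && b == 0) {
    warnf("both fingerprints are all-zero; returning similarity 0")
    return(0)
  }
  cc <- length(intersect(fa$on, fb$on))
  cc / (a + b - cc)
}

# All-pairs Tanimoto via sparse cross-product of the bit matrices:
# crossprod counts shared 1-bits in one shot.
#' @keywords internal
#' @noRd
tanimoto_matrix <- function(set_a, set_b) {
  stopifnot(inherits(set_a, "fingerprint_set"),
            inherits(set_b, "fingerprint_set"))
  if (set_a$nbits != set_b$nbits) {
    stopf("fingerprint length mismatch: %d vs %d", set_a$nbits, set_b$nbits)
  }
  na <- length(set_a$ids)
  nb <- length(set_b$ids)
  ma <- Matrix::sparseMatrix(
    i = unlist(set_a$on), p = c(0L, cumsum(lengths(set_a$on))),
    dims = c(set_a$nbits, na), x = 1
  )
  mb <- Matrix::sparseMatrix(
    i = unlist(set_b$on), p = c(0L, cumsum(lengths(set_b$on))),
    dims = c(set_b$nbits, nb), x = 1
  )
  shared <- as.matrix(Matrix::crossprod(ma, mb))
  pa <- lengths(set_a$on)
  pb <- lengths(set_b$on)
  denom <- outer(pa, pb, `+`) - shared
  out <- ifelse(denom == 0, 0, shared / denom)
  dimnames(out) <- list(set_a$ids, set_b$ids)
  out
}

#' Similarity links above a threshold
#'
#' Links every pair of compounds from two sets whose Tanimoto
#' similarity is at least `threshold` (default 0.9, the cut used when
#' expanding the plant-compound-protein network with close structural
#' analogues).
#'
#' @param set_a,set_b [fingerprint_set()] collections.
#' @param threshold minimum similarity in `[0, 1]`.
#' @return Edge data frame of `compound_similarity` edges, weight equal
#'   to the similarity score.
#' @export
threshold_links <- function(set_a, set_b, threshold = 0.9) {
  stopifnot(threshold >= 0, threshold <= 1)
  sim <- tanimoto_matrix(set_a, set_b)
  hit <- which(sim >= threshold, arr.ind = TRUE)
  same <- set_a$ids[hit[, 1]] == set_b$ids[hit[, 2]]
  hit <- hit[!same, , drop = FALSE]
  data.frame(
    source_kind = rep("compound", nrow(hit)),
    source_id = set_a$ids[hit[, 1]],
    target_kind = rep("compound", nrow(hit)),
    target_id = set_b$ids[hit[, 2]],
    weight = sim[hit],
    origin = rep("compound_similarity", nrow(hit)),
    stringsAsFactors = FALSE
  )
}

#' Best-match similarity links
#'
#' For each query compound, links it to every reference compound
#' attaining the maximum Tanimoto similarity (all ties kept), with the
#' maximum as edge weight.  This is the rule used to attach disease
#' network compounds to their closest plant-compound analogues.  A
#' query whose best score does not exceed `floor` gets no edge: a
#' zero-weight similarity edge could never contribute to traversal.
#'
#' @param set_query,set_ref [fingerprint_set()] collections (queries
#'   and references).
#' @param floor scores must be strictly greater than this to create an
#'   edge (default 0).
#' @return Edge data frame of `compound_similarity` edges.
#' @export
best_match_links <- function(set_query, set_ref, floor = 0) {
  sim <- tanimoto_matrix(set_query, set_ref)
  rows <- lapply(seq_along(set_query$ids), function(i) {
    s <- sim[i, ]
    s[set_ref$ids == set_query$ids[i]] <- -Inf  # never self-link
    m <- max(s)
    if (!is.finite(m) || m <= floor) return(NULL)
    j <- which(s == m)
    data.frame(
      source_kind = rep("compound", length(j)),
      source_id = rep(set_query$ids[i], length(j)),
      target_kind = rep("compound", length(j)),
      target_id = set_ref$ids[j],
      weight = rep(m, length(j)),
      origin = rep("compound_similarity", length(j)),
      stringsAsFactors = FALSE
    )
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0) {
    return(data.frame(source_kind = character(), source_id = character(),
                      target_kind = character(), target_id = character(),
                      weight = numeric(), origin = character(),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' @export
print.fingerprint <- function(x, ...) {
  cat(sprintf("fingerprint %s: %d/%d bits set\n",
              x$compound_id, x$popcount, x$nbits))
  invisible(x)
}

#' @export
print.fingerprint_set <- function(x, ...) {
  cat(sprintf("fingerprint_set: %d compounds, %d bits, mean density %.4f\n",
              length(x$ids), x$nbits,
              mean(lengths(x$on)) / x$nbits))
  invisible(x)
}
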