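# Internal helpers shared across modules.

#' @keywords internal
#' @noRd
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Canonical form of a node identifier: trimmed, internal whitespace
# collapsed, case-folded.  Inputs mix CID/GI strings and Latin plant
# names; identifiers must arrive pre-converted to a common scheme.
#' @keywords internal
#' @noRd
canonical_id <- function(id) {
  tolower(gsub("\\s+", " ", trimws(as.character(id))))
}

#' @keywords internal
#' @noRd
node_key <- function(kind, id) {
  paste0(kind, "|", canonical_id(id))
}

# Run expr with a fixed RNG seed, restoring the caller's RNG state.
#' @keywords internal
#' @noRd
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(seed)
  expr
}

#' @keywords internal
#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

#' @keywords internal
#' @noRd
stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

#' @keywords internal
#' @noRd
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
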