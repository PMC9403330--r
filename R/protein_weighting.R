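#' Normalised protein weights from network centralities
#'
#' Disease target proteins are weighted by their topological importance
#' in the human protein-protein interaction network: the betweenness
#' (BC) and closeness (CC) centralities of each gene are averaged and
#' the averages divided by the maximum average, so the most central
#' protein gets weight 1 and all weights lie in (0, 1].  These weights
#' are the per-protein factors of the formula score.
#'
#' Division by the maximum average (rather than min-max scaling) is the
#' normalisation that reproduces the published weight table for the 21
#' type II diabetes genes shipped with the package; min-max scaling
#' would force the least central gene to 0, contradicting it.
#'
#' @param raw data frame with columns `gene`, `bc`, `cc` (non-negative
#'   centralities), and optionally `protein_id` (e.g. a GI number)
#'   carried through for traversal seeding.
#' @return A data frame of class `protein_weights` with columns `gene`,
#'   (`protein_id`,) `bc`, `cc`, `avg` and `norm`, row order preserved.
#' @examples
#' tab <- normalize_weights(read_centralities(
#'   system.file("extdata", "t2dm_protein_centrality.tsv",
#'               package = "herbnet")))
#' round_weights(tab)[1:3, ]
#' @export
normalize_weights <- function(raw) {
  req <- c("gene", "bc", "cc")
  miss <- setdiff(req, names(raw))
  if (length(miss) > 0) {
    stopf("centrality table is missing column(s): %s",
          paste(miss, collapse = ", "))
  }
  if (nrow(raw) == 0) stopf("centrality table is empty")
  bc <- as.numeric(raw$bc)
  cc <- as.numeric(raw$cc)
  if (any(!is.finite(bc) | bc < 0) || any(!is.finite(cc) | cc < 0)) {
    stopf("centralities must be finite and non-negative")
  }
  if (anyDuplicated(raw$gene)) stopf("duplicate gene symbols")
  avg <- (bc + cc) / 2
  mx <- max(avg)
  if (mx <= 0) stopf("all centralities are zero; normalization undefined")
  out <- data.frame(gene = as.character(raw$gene), bc = bc, cc = cc,
                    avg = avg, norm = avg / mx, stringsAsFactors = FALSE)
  if (!is.null(raw$protein_id)) {
    out$protein_id <- as.character(raw$protein_id)
    out <- out[c("gene", "protein_id", "bc", "cc", "avg", "norm")]
  }
  class(out) <- c("protein_weights", "data.frame")
  out
}

#' @rdname normalize_weights
#' @param x a `protein_weights` table.
#' @param digits decimals for display rounding (half-up; internal
#'   arithmetic stays full precision).
#' @export
round_weights <- function(x, digits = 3) {
  x$avg <- round_half_up(x$avg, digits + 1)
  x$norm <- round_half_up(x$norm, digits)
  x
}

#' Read a protein centrality table
#'
#' Tab-separated, UTF-8, header row with columns `gene`, `bc`, `cc` and
#' optionally `protein_id`.  The packaged file
#' `extdata/t2dm_protein_centrality.tsv` holds the 21 type II diabetes
#' mellitus target genes with their published centralities.
#'
#' @param path file path.
#' @return Data frame with the table's columns.
#' @export
read_centralities <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           comment.char = "#")
  req <- c("gene", "bc", "cc")
  miss <- setdiff(req, names(tab))
  if (length(miss) > 0) {
    stopf("%s: missing column(s): %s", path, paste(miss, collapse = ", "))
  }
  bad <- which(!is.finite(suppressWarnings(as.numeric(tab$bc))) |
               !is.finite(suppressWarnings(as.numeric(tab$cc))))
  if (length(bad) > 0) {
    stopf("%s: non-numeric centrality at data line(s): %s", path,
          paste(utils::head(bad, 5), collapse = ", "))
  }
  tab$bc <- as.numeric(tab$bc)
  tab$cc <- as.numeric(tab$cc)
  tab
}

#' @export
print.protein_weights <- function(x, digits = 3, ...) {
  cat(sprintf("protein_weights: %d genes, max attainable score %.4f\n",
              nrow(x), sum(x$norm)))
  print.data.frame(round_weights(x, digits), ...)
  invisible(x)
}
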