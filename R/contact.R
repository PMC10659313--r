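#' Residue contact graph from coordinates
#'
#' Builds a symmetric 0/1 adjacency over residues from per-residue 3D
#' coordinates (e.g. alpha-carbon positions): residues i != j are adjacent
#' iff their Euclidean distance is positive and at most the threshold. The
#' diagonal is zero. This is the structural input of the graph-convolutional
#' architecture.
#'
#' @param coords Numeric matrix, one row per residue, 3 columns (Angstrom).
#' @param threshold Contact distance threshold in Angstrom (default 8).
#' @return L x L adjacency matrix of class `contact_graph` with a
#'   `threshold` attribute.
#' @export
contact_graph <- function(coords, threshold = 8) {
  coords <- as.matrix(coords)
  if (any(!is.finite(coords))) stop("missing or non-finite coordinates")
  if (ncol(coords) != 3L) stop("coords must have 3 columns")
  D <- as.matrix(dist(coords))
  A <- (D > 0 & D <= threshold) * 1
  diag(A) <- 0
  structure(A, class = "contact_graph", threshold = threshold)
}

#' Linear-chain contact graph
#'
#' Convenience adjacency connecting residues within `width` sequence
#' positions of each other; a reasonable synthetic stand-in when no
#' structure is available.
#'
#' @param L Number of residues.
#' @param width Band width in sequence positions (default 2).
#' @return L x L adjacency matrix of class `contact_graph`.
#' @export
chain_contact_graph <- function(L, width = 2) {
  A <- outer(seq_len(L), seq_len(L),
             function(i, j) as.numeric(abs(i - j) <= width & i != j))
  structure(A, class = "contact_graph", threshold = NA_real_)
}
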