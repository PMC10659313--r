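#' One-hot encode a protein sequence
#'
#' Encodes a sequence as an L x 20 binary matrix over the canonical
#' alphabet: row p has a single 1 in the column of the residue at position
#' p. This is the input representation for all predictors in the package.
#'
#' @param seq Amino-acid sequence (single string).
#' @param alphabet Ordered amino-acid alphabet; defaults to [AA_ALPHABET].
#' @return L x 20 binary matrix with `alphabet` as column names.
#' @examples
#' m <- one_hot_encode("ACDY")
#' rowSums(m)  # all 1
#' @export
one_hot_encode <- function(seq, alphabet = AA_ALPHABET) {
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  idx <- match(chars, alphabet)
  if (anyNA(idx)) {
    stop("unknown character(s) in sequence: ",
         paste(unique(chars[is.na(idx)]), collapse = ", "))
  }
  m <- matrix(0L, nrow = length(idx), ncol = length(alphabet),
              dimnames = list(NULL, alphabet))
  m[cbind(seq_along(idx), idx)] <- 1L
  m
}

#' Decode a one-hot matrix back to a sequence
#'
#' @param m L x 20 one-hot matrix as produced by [one_hot_encode()].
#' @param alphabet Ordered amino-acid alphabet.
#' @return The encoded sequence as a single string.
#' @export
one_hot_decode <- function(m, alphabet = AA_ALPHABET) {
  stopifnot(is.matrix(m), ncol(m) == length(alphabet))
  paste(alphabet[max.col(m)], collapse = "")
}

# Batch-encode sequences into an n x (L*20) matrix, position-major:
# column (p-1)*20 + a is position p, alphabet index a. This flattening is
# the fixed input layout shared by every model architecture.
encode_sequences <- function(seqs, L = NULL) {
  M <- seqs_to_int_matrix(seqs)
  if (!is.null(L) && ncol(M) != L) {
    stop("sequence length ", ncol(M), " does not match model length ", L)
  }
  n <- nrow(M)
  L <- ncol(M)
  X <- matrix(0, nrow = n, ncol = L * 20L)
  cols <- (rep(seq_len(L), each = n) - 1L) * 20L + as.vector(M)
  X[cbind(rep(seq_len(n), times = L), cols)] <- 1
  X
}
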