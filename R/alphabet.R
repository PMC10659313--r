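#' Canonical amino-acid alphabet
#'
#' The 20 canonical amino acids as one-letter codes, ordered alphabetically
#' by code. This ordering is frozen: every one-hot encoding, additive-effect
#' table and model parameter block in the package indexes amino acids in
#' this order, so index lookup is a bijection.
#'
#' @format Character vector of length 20.
#' @export
AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Convert between residues and alphabet indices
#'
#' @param aa Character vector of one-letter amino-acid codes.
#' @return Integer vector of indices into [AA_ALPHABET] (1-based).
#' @seealso [AA_ALPHABET]
#' @export
aa_index <- function(aa) {
  idx <- match(aa, AA_ALPHABET)
  if (anyNA(idx)) {
    bad <- unique(aa[is.na(idx)])
    stop("unknown amino acid(s): ", paste(bad, collapse = ", "))
  }
  idx
}

# Integer-encode a single sequence (1..20 per residue).
seq_to_int <- function(seq) {
  aa_index(strsplit(seq, "", fixed = TRUE)[[1]])
}

# Integer-encode a vector of equal-length sequences into an n x L matrix.
seqs_to_int_matrix <- function(seqs) {
  if (length(seqs) == 0L) stop("empty sequence collection")
  L <- nchar(seqs[1])
  if (any(nchar(seqs) != L)) stop("sequences must all have the same length")
  chars <- matrix(unlist(strsplit(seqs, "", fixed = TRUE), use.names = FALSE),
                  nrow = length(seqs), ncol = L, byrow = TRUE)
  matrix(aa_index(chars), nrow = length(seqs), ncol = L)
}

int_to_seq <- function(idx) {
  paste(AA_ALPHABET[idx], collapse = "")
}

int_matrix_to_seqs <- function(m) {
  ch <- matrix(AA_ALPHABET[m], nrow = nrow(m))
  do.call(paste0, as.data.frame(ch, stringsAsFactors = FALSE))
}
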