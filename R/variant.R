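#' Protein variant as wild type plus substitutions
#'
#' A variant is represented by its wild-type sequence together with a set of
#' point substitutions. Positions are 0-based internally (all user-facing
#' mutation strings are 1-based, following protein convention). The number
#' of substitutions equals the Hamming distance to wild type by construction.
#'
#' @param wild_type Wild-type amino-acid sequence (single string).
#' @param pos Integer vector of 0-based substituted positions (unique).
#' @param aa Character vector of substituted amino acids, same length as
#'   `pos`; each must differ from the wild-type residue at that position.
#' @return An object of class `protein_variant` with fields `wild_type`,
#'   `pos`, `aa`.
#' @examples
#' v <- protein_variant("MTYKLILNGK", pos = c(1, 4), aa = c("A", "W"))
#' variant_sequence(v)
#' mutation_string(v)
#' @export
protein_variant <- function(wild_type, pos = integer(), aa = character()) {
  stopifnot(is.character(wild_type), length(wild_type) == 1L)
  pos <- as.integer(pos)
  L <- nchar(wild_type)
  if (length(pos) != length(aa)) stop("pos and aa must have equal length")
  if (anyDuplicated(pos)) stop("substitution positions must be unique")
  if (length(pos) && (min(pos) < 0L || max(pos) >= L)) {
    stop("substitution position out of range [0, ", L - 1L, "]")
  }
  wt_chars <- strsplit(wild_type, "", fixed = TRUE)[[1]]
  aa_index(aa)  # validates the alphabet
  if (any(aa == wt_chars[pos + 1L])) {
    stop("substitution equal to the wild-type residue at its position")
  }
  ord <- order(pos)
  structure(list(wild_type = wild_type, pos = pos[ord], aa = aa[ord]),
            class = "protein_variant")
}

#' @export
print.protein_variant <- function(x, ...) {
  cat("<protein_variant> ", mutation_string(x),
      " (", length(x$pos), " mutations, L=", nchar(x$wild_type), ")\n",
      sep = "")
  invisible(x)
}

#' Number of substitutions carried by a variant
#'
#' @param variant A [protein_variant()].
#' @return Non-negative integer; equals the Hamming distance to wild type.
#' @export
n_mutations <- function(variant) {
  stopifnot(inherits(variant, "protein_variant"))
  length(variant$pos)
}

#' Hamming distance between two equal-length sequences
#'
#' Counts the positions at which two sequences differ. Symmetric, and a
#' metric on sequences of a fixed length.
#'
#' @param a,b Sequences as single strings of equal length.
#' @return Non-negative integer.
#' @examples
#' hamming_distance("MTYK", "MAYK")
#' @export
hamming_distance <- function(a, b) {
  stopifnot(is.character(a), is.character(b),
            length(a) == 1L, length(b) == 1L)
  if (nchar(a) != nchar(b)) {
    stop("length mismatch: ", nchar(a), " vs ", nchar(b))
  }
  sum(charToRaw(a) != charToRaw(b))
}

#' Apply a substitution set to a wild-type sequence
#'
#' @param wild_type Wild-type sequence (single string).
#' @param pos 0-based positions to substitute (unique, in range).
#' @param aa Replacement amino acids (must differ from wild type at `pos`).
#' @return The mutated sequence; differs from `wild_type` exactly at `pos`.
#' @examples
#' apply_substitutions("AAAA", pos = 1, aa = "C")
#' @export
apply_substitutions <- function(wild_type, pos = integer(), aa = character()) {
  v <- protein_variant(wild_type, pos, aa)
  variant_sequence(v)
}

#' Full sequence of a variant
#'
#' @param variant A [protein_variant()].
#' @return The variant's amino-acid sequence as a single string.
#' @export
variant_sequence <- function(variant) {
  stopifnot(inherits(variant, "protein_variant"))
  chars <- strsplit(variant$wild_type, "", fixed = TRUE)[[1]]
  chars[variant$pos + 1L] <- variant$aa
  paste(chars, collapse = "")
}

#' Build a variant from a full sequence
#'
#' @param wild_type Wild-type sequence.
#' @param sequence Mutant sequence of the same length.
#' @return A [protein_variant()] carrying the differing positions.
#' @export
variant_from_sequence <- function(wild_type, sequence) {
  if (nchar(wild_type) != nchar(sequence)) {
    stop("length mismatch: ", nchar(wild_type), " vs ", nchar(sequence))
  }
  wt <- strsplit(wild_type, "", fixed = TRUE)[[1]]
  mt <- strsplit(sequence, "", fixed = TRUE)[[1]]
  d <- which(wt != mt)
  protein_variant(wild_type, pos = d - 1L, aa = mt[d])
}

#' Mutation-string notation
#'
#' Formats a variant in the standard protein notation
#' `"<wt aa><1-based position><mutant aa>"`, comma-separated, e.g.
#' `"A23Y,K31M"`. The wild type itself is written `"WT"`.
#'
#' @param variant A [protein_variant()].
#' @return Single string.
#' @export
mutation_string <- function(variant) {
  stopifnot(inherits(variant, "protein_variant"))
  if (length(variant$pos) == 0L) return("WT")
  wt <- strsplit(variant$wild_type, "", fixed = TRUE)[[1]]
  paste0(wt[variant$pos + 1L], variant$pos + 1L, variant$aa, collapse = ",")
}

#' Parse mutation-string notation
#'
#' Inverse of [mutation_string()]: parses `"A23Y,K31M"`-style tokens
#' (1-based positions) against a wild-type sequence, validating that the
#' stated wild-type residues match.
#'
#' @param x Mutation string; `"WT"` or `""` denotes the wild type.
#' @param wild_type Wild-type sequence.
#' @return A [protein_variant()].
#' @export
parse_mutation_string <- function(x, wild_type) {
  stopifnot(is.character(x), length(x) == 1L)
  x <- trimws(x)
  if (x == "" || toupper(x) == "WT") {
    return(protein_variant(wild_type))
  }
  tokens <- strsplit(x, ",", fixed = TRUE)[[1]]
  m <- regmatches(tokens, regexec("^([A-Y])([0-9]+)([A-Y])$", tokens))
  bad <- vapply(m, length, 1L) != 4L
  if (any(bad)) {
    stop("unparseable mutation token(s): ", paste(tokens[bad], collapse = ", "))
  }
  wt_aa <- vapply(m, `[[`, "", 2L)
  pos1 <- as.integer(vapply(m, `[[`, "", 3L))
  mut_aa <- vapply(m, `[[`, "", 4L)
  wt_chars <- strsplit(wild_type, "", fixed = TRUE)[[1]]
  if (any(pos1 < 1L | pos1 > length(wt_chars))) {
    stop("mutation position out of range in: ", x)
  }
  mismatch <- wt_chars[pos1] != wt_aa
  if (any(mismatch)) {
    stop("wild-type residue mismatch in token(s): ",
         paste(tokens[mismatch], collapse = ", "))
  }
  protein_variant(wild_type, pos = pos1 - 1L, aa = mut_aa)
}

# Vectorized mutation strings for many sequences against one wild type.
# Returns "WT" for rows identical to the wild type.
mutation_strings_from_seqs <- function(seqs, wild_type) {
  n <- length(seqs)
  if (n == 0L) return(character())
  M <- seqs_to_int_matrix(seqs)
  wt_idx <- seq_to_int(wild_type)
  diff <- sweep(M, 2L, wt_idx, `!=`)
  hits <- which(diff, arr.ind = TRUE)
  out <- rep("WT", n)
  if (nrow(hits)) {
    ord <- order(hits[, 1L], hits[, 2L])
    hits <- hits[ord, , drop = FALSE]
    tok <- paste0(AA_ALPHABET[wt_idx[hits[, 2L]]], hits[, 2L],
                  AA_ALPHABET[M[hits]])
    grouped <- vapply(split(tok, hits[, 1L]), paste, "", collapse = ",")
    out[as.integer(names(grouped))] <- grouped
  }
  out
}
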