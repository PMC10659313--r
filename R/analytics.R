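#' Per-position Shannon entropy of an aligned sequence set
#'
#' Quantifies amino-acid diversity at each position of an equal-length
#' sequence collection, in bits. Low entropy means a site tolerates few
#' amino acids across the set (e.g. designs repeatedly proposing the same
#' mutation); the maximum, log2(20) ~ 4.32 bits, is reached when all 20
#' residues are equally frequent.
#'
#' @param seqs Character vector of equal-length sequences (nonempty).
#' @param base Logarithm base; 2 (bits, default) or any base > 1.
#' @return Numeric vector of per-position entropies, length L.
#' @examples
#' site_entropy(c("AC", "AD", "AE"))
#' @export
site_entropy <- function(seqs, base = 2) {
  if (length(seqs) == 0L) stop("empty sequence collection")
  M <- seqs_to_int_matrix(seqs)
  apply(M, 2L, function(col) {
    p <- tabulate(col, nbins = 20L)
    p <- p[p > 0] / length(col)
    -sum(p * log(p, base = base))
  })
}

#' Locate KEX2 protease recognition sites
#'
#' Scans a protein sequence for Lys/Arg-Arg dipeptides (`[KR]R`), the motif
#' cleaved by the yeast Golgi protease KEX2. Overlapping matches are all
#' reported. Note this is a pure sequence scan; whether a site is actually
#' cleaved additionally depends on structural exposure, which the package
#' does not evaluate.
#'
#' @param seq Protein sequence (single string).
#' @return Integer vector of 0-based start positions (possibly empty).
#' @examples
#' find_kex2_sites("AKRA")  # 1
#' find_kex2_sites("KRR")   # 0 1 (overlap allowed)
#' @export
find_kex2_sites <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L)
  m <- gregexpr("(?=[KR]R)", seq, perl = TRUE)[[1]]
  if (m[1] == -1L) return(integer())
  as.integer(m) - 1L
}

#' Metric MDS embedding of sequences by Hamming distance
#'
#' Embeds a sequence collection in `dim` dimensions so that pairwise
#' Euclidean distances approximate pairwise Hamming distances. Uses a
#' classical (Torgerson) initialization followed by SMACOF stress
#' majorization; the raw stress is recorded at every iteration and is
#' non-increasing by construction.
#'
#' @param seqs Character vector of >= `dim` + 1 equal-length sequences.
#' @param dim Embedding dimension (default 2).
#' @param max_iter Maximum majorization iterations.
#' @param tol Relative stress-improvement tolerance for early stop.
#' @return List with `points` (n x dim coordinate matrix) and `stress`
#'   (numeric vector, one entry per iteration, non-increasing).
#' @export
mds_embed <- function(seqs, dim = 2, max_iter = 200, tol = 1e-8) {
  n <- length(seqs)
  if (n < dim + 1L) stop("need at least ", dim + 1L, " sequences")
  X1 <- encode_sequences(seqs)
  # Manhattan distance between one-hot encodings is twice the Hamming distance
  D <- as.matrix(dist(X1, method = "manhattan")) / 2
  pts <- suppressWarnings(cmdscale(D, k = dim))
  if (ncol(pts) < dim) {  # degenerate spectra (e.g. all-identical input)
    pts <- cbind(pts, matrix(0, n, dim - ncol(pts)))
  }
  stress_of <- function(P) {
    dE <- as.matrix(dist(P))
    sum((dE[upper.tri(dE)] - D[upper.tri(D)])^2)
  }
  stress <- stress_of(pts)
  for (it in seq_len(max_iter)) {
    dE <- as.matrix(dist(pts))
    B <- ifelse(dE > 0, -D / pmax(dE, .Machine$double.eps), 0)
    diag(B) <- 0
    diag(B) <- -rowSums(B)
    pts_new <- (B %*% pts) / n
    s_new <- stress_of(pts_new)
    stress <- c(stress, s_new)
    improved <- stress[length(stress) - 1L] - s_new
    pts <- pts_new
    if (improved <= tol * max(s_new, 1)) break
  }
  list(points = pts, stress = stress)
}

#' Deterministic reverse translation of a protein sequence
#'
#' Maps a protein back to a nucleotide sequence using the standard genetic
#' code. The codon chosen at each position is a deterministic function of
#' `seed`; incrementing `variant_index` rotates every degenerate codon
#' choice, so distinct indices give distinct synonymous sequences whenever
#' the protein contains a degenerately encoded residue. This supports
#' synonymous internal-control constructs that share an amino-acid sequence
#' but differ at the nucleotide level.
#'
#' @param protein Protein sequence (single string; no stop symbol).
#' @param variant_index Non-negative integer selecting a synonymous variant.
#' @param seed Integer seed fixing the per-position base codon choice.
#' @return Nucleotide sequence (DNA, single string) translating to `protein`.
#' @export
reverse_translate <- function(protein, variant_index = 0, seed = 0) {
  aa <- strsplit(protein, "", fixed = TRUE)[[1]]
  aa_index(aa)  # validate
  tab <- codon_table()
  with_seed(seed, {
    codons <- vapply(aa, function(a) {
      opts <- tab[[a]]
      base <- sample.int(length(opts), 1L)
      opts[((base - 1L + variant_index) %% length(opts)) + 1L]
    }, "")
  })
  paste(codons, collapse = "")
}

# Sorted codon lists per amino acid from the standard genetic code.
codon_table <- function() {
  gc <- Biostrings::GENETIC_CODE
  gc <- gc[gc != "*"]
  split(sort(names(gc)), gc[sort(names(gc))])
}
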