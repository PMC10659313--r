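#' Simulate a ground-truth epistatic fitness landscape
#'
#' Builds a synthetic sequence-fitness function over a wild-type protein:
#' fitness = baseline + sum of additive per-substitution effects + sum of
#' sparse pairwise epistatic terms. A pairwise term contributes only when
#' both of its participating substitutions are present (specific epistasis).
#' Additive effects are drawn with a negative mean by default, reflecting
#' that most mutations are deleterious/destabilizing. The landscape serves
#' as the exact oracle for model training, design and evaluation tests.
#'
#' @param wild_type Wild-type amino-acid sequence.
#' @param additive_sd SD of additive effects (default 1).
#' @param additive_mean Mean of additive effects (default -0.5).
#' @param epistasis_density Fraction of the C(L,2) * 19^2 possible pairwise
#'   terms that are active (default 0.02).
#' @param epistasis_sd SD of epistatic effect sizes (default 1).
#' @param baseline Wild-type fitness level (default 0, arbitrary units).
#' @param seed Integer seed; the landscape is fully reproducible given it.
#' @return Object of class `true_landscape` with fields `wild_type`,
#'   `baseline`, `additive` (L x 20 matrix, zero at wild-type residues) and
#'   `epistasis` (data frame of pos_i/aa_i/pos_j/aa_j/effect, 0-based
#'   positions, pos_i < pos_j).
#' @examples
#' ls <- generate_landscape("MTYKLILNG", seed = 1)
#' true_fitness(ls, "MTYKLILNG")  # baseline
#' @export
generate_landscape <- function(wild_type,
                               additive_sd = 1,
                               additive_mean = -0.5,
                               epistasis_density = 0.02,
                               epistasis_sd = 1,
                               baseline = 0,
                               seed = 1) {
  stopifnot(additive_sd >= 0, epistasis_sd >= 0)
  if (epistasis_density < 0 || epistasis_density > 1) {
    stop("epistasis_density must be in [0, 1]")
  }
  wt_idx <- seq_to_int(wild_type)
  L <- length(wt_idx)
  with_seed(seed, {
    additive <- matrix(rnorm(L * 20L, mean = additive_mean, sd = additive_sd),
                       nrow = L, ncol = 20L,
                       dimnames = list(NULL, AA_ALPHABET))
    additive[cbind(seq_len(L), wt_idx)] <- 0
    pairs <- combn(L, 2L)        # 1-based position pairs, i < j
    n_pairs <- ncol(pairs)
    n_possible <- n_pairs * 19L * 19L
    n_terms <- rbinom(1L, n_possible, epistasis_density)
    epi <- if (n_terms > 0L) {
      idx <- sample.int(n_possible, n_terms)
      pair_id <- (idx - 1L) %/% 361L + 1L
      r <- (idx - 1L) %% 361L
      ai_rank <- r %/% 19L + 1L   # rank among the 19 non-wild-type residues
      aj_rank <- r %% 19L + 1L
      pi_ <- pairs[1L, pair_id]
      pj_ <- pairs[2L, pair_id]
      non_wt <- function(p, rank) {
        # alphabet index of the rank-th non-wild-type residue at position p
        opts <- setdiff(seq_len(20L), wt_idx[p])
        opts[rank]
      }
      ai <- mapply(non_wt, pi_, ai_rank)
      aj <- mapply(non_wt, pj_, aj_rank)
      data.frame(pos_i = pi_ - 1L, aa_i = AA_ALPHABET[ai],
                 pos_j = pj_ - 1L, aa_j = AA_ALPHABET[aj],
                 effect = rnorm(n_terms, 0, epistasis_sd),
                 stringsAsFactors = FALSE)
    } else {
      data.frame(pos_i = integer(), aa_i = character(),
                 pos_j = integer(), aa_j = character(),
                 effect = numeric(), stringsAsFactors = FALSE)
    }
  })
  structure(list(wild_type = wild_type, baseline = baseline,
                 additive = additive, epistasis = epi, seed = seed),
            class = "true_landscape")
}

#' @export
print.true_landscape <- function(x, ...) {
  cat("<true_landscape> L=", nchar(x$wild_type),
      ", ", nrow(x$epistasis), " pairwise epistatic terms, baseline ",
      x$baseline, "\n", sep = "")
  invisible(x)
}

# Integer pair key for fast epistasis lookup: positions 1-based here.
epi_keys <- function(pos_i1, ai, pos_j1, aj) {
  (pos_i1 * 20L + ai) * 100000L + (pos_j1 * 20L + aj)
}

#' Evaluate the true fitness of variants on a landscape
#'
#' @param landscape A [generate_landscape()] object.
#' @param x A [protein_variant()], or a character vector of full sequences
#'   with the landscape's length.
#' @return Numeric fitness value(s): baseline + additive sum + active
#'   pairwise epistatic terms.
#' @export
true_fitness <- function(landscape, x) {
  stopifnot(inherits(landscape, "true_landscape"))
  if (inherits(x, "protein_variant")) {
    if (x$wild_type != landscape$wild_type) {
      stop("variant wild type does not match the landscape wild type")
    }
    x <- variant_sequence(x)
  }
  wt_idx <- seq_to_int(landscape$wild_type)
  L <- length(wt_idx)
  M <- seqs_to_int_matrix(x)
  if (ncol(M) != L) stop("sequence length does not match the landscape")
  n <- nrow(M)
  # additive part: additive[p, wt] == 0, so summing over all positions works
  lin <- (as.vector(M) - 1L) * L + rep(seq_len(L), each = n)
  fit <- landscape$baseline +
    rowSums(matrix(landscape$additive[lin], nrow = n, ncol = L))
  epi <- landscape$epistasis
  if (nrow(epi)) {
    diff <- sweep(M, 2L, wt_idx, `!=`)
    varying <- which(colSums(diff) > 0L)           # 1-based positions
    keep <- (epi$pos_i + 1L) %in% varying & (epi$pos_j + 1L) %in% varying
    for (t in which(keep)) {
      active <- M[, epi$pos_i[t] + 1L] == aa_index(epi$aa_i[t]) &
        M[, epi$pos_j[t] + 1L] == aa_index(epi$aa_j[t])
      if (any(active)) fit[active] <- fit[active] + epi$effect[t]
    }
  }
  fit
}

#' Sample a local (single + double mutant) fitness dataset
#'
#' Emulates a deep-mutational-scanning experiment around the wild type:
#' the dataset contains the wild type, every one of the L*19 single
#' mutants, and a uniform random fraction of the C(L,2)*19^2 double
#' mutants. Scores are true fitness plus additive Gaussian noise.
#'
#' @param landscape A [generate_landscape()] object.
#' @param double_fraction Fraction of all possible doubles to include,
#'   in (0, 1].
#' @param noise_sd Measurement noise SD (default 0.1).
#' @param seed Integer seed.
#' @return Data frame (a fitness dataset) with columns `variant`
#'   (mutation string), `sequence`, `score`, `n_mut`.
#' @export
sample_local_dataset <- function(landscape, double_fraction = 0.1,
                                 noise_sd = 0.1, seed = 1) {
  stopifnot(inherits(landscape, "true_landscape"))
  if (double_fraction <= 0 || double_fraction > 1) {
    stop("double_fraction must be in (0, 1]")
  }
  wt <- landscape$wild_type
  wt_idx <- seq_to_int(wt)
  L <- length(wt_idx)
  # all singles
  pos1 <- rep(seq_len(L), each = 19L)
  aa1 <- unlist(lapply(seq_len(L),
                       function(p) setdiff(seq_len(20L), wt_idx[p])))
  Msingle <- matrix(wt_idx, nrow = L * 19L, ncol = L, byrow = TRUE)
  Msingle[cbind(seq_len(L * 19L), pos1)] <- aa1
  # sampled doubles
  pairs <- combn(L, 2L)
  n_possible <- ncol(pairs) * 361L
  with_seed(seed, {
    n_d <- max(1L, round(double_fraction * n_possible))
    idx <- sample.int(n_possible, n_d)
    pair_id <- (idx - 1L) %/% 361L + 1L
    r <- (idx - 1L) %% 361L
    ai_rank <- r %/% 19L + 1L
    aj_rank <- r %% 19L + 1L
    pi_ <- pairs[1L, pair_id]
    pj_ <- pairs[2L, pair_id]
    non_wt <- lapply(seq_len(L), function(p) setdiff(seq_len(20L), wt_idx[p]))
    ai <- mapply(function(p, k) non_wt[[p]][k], pi_, ai_rank)
    aj <- mapply(function(p, k) non_wt[[p]][k], pj_, aj_rank)
    Mdouble <- matrix(wt_idx, nrow = n_d, ncol = L, byrow = TRUE)
    Mdouble[cbind(seq_len(n_d), pi_)] <- ai
    Mdouble[cbind(seq_len(n_d), pj_)] <- aj
    M <- rbind(matrix(wt_idx, nrow = 1L), Msingle, Mdouble)
    seqs <- int_matrix_to_seqs(M)
    truth <- true_fitness(landscape, seqs)
    score <- truth + if (noise_sd > 0) rnorm(length(truth), 0, noise_sd) else 0
  })
  data.frame(variant = mutation_strings_from_seqs(seqs, wt),
             sequence = seqs,
             score = score,
             n_mut = c(0L, rep(1L, L * 19L), rep(2L, nrow(M) - 1L - L * 19L)),
             stringsAsFactors = FALSE)
}

#' Enumerate a combinatorial saturation dataset at fixed sites
#'
#' Emulates a complete k-site combinatorial saturation-mutagenesis library:
#' all 20^k amino-acid combinations at the given sites (every other
#' position wild type), including the wild type itself, with optional
#' uniform subsampling to mimic a partially characterized library.
#'
#' @param landscape A [generate_landscape()] object.
#' @param sites Integer vector of distinct 0-based positions (typically 4).
#' @param coverage_fraction Fraction of the 20^k combinations retained,
#'   in (0, 1]; 1 keeps all of them.
#' @param noise_sd Measurement noise SD (default 0.1).
#' @param seed Integer seed.
#' @return Data frame with columns `variant`, `sequence`, `score`, `n_mut`.
#' @export
combinatorial_dataset <- function(landscape, sites, coverage_fraction = 1,
                                  noise_sd = 0.1, seed = 1) {
  stopifnot(inherits(landscape, "true_landscape"))
  sites <- as.integer(sites)
  if (anyDuplicated(sites)) stop("duplicate sites")
  wt <- landscape$wild_type
  wt_idx <- seq_to_int(wt)
  L <- length(wt_idx)
  if (any(sites < 0L | sites >= L)) stop("site out of range")
  k <- length(sites)
  combos <- as.matrix(expand.grid(rep(list(seq_len(20L)), k)))
  n_all <- nrow(combos)
  with_seed(seed, {
    if (coverage_fraction < 1) {
      keep <- sort(sample.int(n_all, round(coverage_fraction * n_all)))
      combos <- combos[keep, , drop = FALSE]
    }
    n <- nrow(combos)
    M <- matrix(wt_idx, nrow = n, ncol = L, byrow = TRUE)
    M[, sites + 1L] <- combos
    seqs <- int_matrix_to_seqs(M)
    truth <- true_fitness(landscape, seqs)
    score <- truth + if (noise_sd > 0) rnorm(n, 0, noise_sd) else 0
    n_mut <- as.integer(rowSums(
      combos != matrix(wt_idx[sites + 1L], n, k, byrow = TRUE)))
  })
  data.frame(variant = mutation_strings_from_seqs(seqs, wt),
             sequence = seqs, score = score, n_mut = n_mut,
             stringsAsFactors = FALSE)
}

#' Assign train/validation/test splits to a fitness dataset
#'
#' Random split by variant with a fixed seed (default 80/10/10).
#'
#' @param data Fitness dataset data frame.
#' @param fractions Named or ordered numeric vector `(train, val, test)`
#'   summing to 1.
#' @param seed Integer seed.
#' @return The data frame with a `split` column added.
#' @export
assign_splits <- function(data, fractions = c(train = 0.8, val = 0.1,
                                              test = 0.1), seed = 1) {
  stopifnot(length(fractions) == 3L, abs(sum(fractions) - 1) < 1e-8)
  n <- nrow(data)
  with_seed(seed, {
    idx <- sample.int(n)
  })
  n_train <- round(fractions[1] * n)
  n_val <- round(fractions[2] * n)
  split <- rep("test", n)
  split[idx[seq_len(n_train)]] <- "train"
  if (n_val > 0) split[idx[n_train + seq_len(n_val)]] <- "val"
  data$split <- split
  data
}
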