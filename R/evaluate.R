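#' Mutation-count-stratified Spearman correlation
#'
#' Rank correlation between predicted and observed fitness computed
#' separately within each mutation-count stratum. Strata smaller than
#' `min_stratum` are reported with `rho = NA` rather than silently
#' dropped. Ties are handled by average ranks (the standard Spearman
#' convention).
#'
#' @param predicted,observed Aligned numeric vectors.
#' @param mutation_counts Integer vector of Hamming distances from wild
#'   type, aligned with the scores.
#' @param min_stratum Minimum stratum size for a correlation (default 3).
#' @return Data frame with columns `n_mut`, `n`, `rho`, one row per
#'   stratum in increasing mutation count.
#' @export
stratified_spearman <- function(predicted, observed, mutation_counts,
                                min_stratum = 3) {
  n <- length(predicted)
  stopifnot(length(observed) == n, length(mutation_counts) == n)
  strata <- sort(unique(mutation_counts))
  rows <- lapply(strata, function(k) {
    idx <- mutation_counts == k
    m <- sum(idx)
    rho <- if (m >= min_stratum) {
      cor(predicted[idx], observed[idx], method = "spearman")
    } else {
      NA_real_
    }
    data.frame(n_mut = k, n = m, rho = rho)
  })
  do.call(rbind, rows)
}

#' Recall of the true top variants within a design budget
#'
#' Given aligned predicted and observed fitness over a variant population,
#' ranks all variants by prediction, keeps the top `budget`, and reports
#' the fraction of the true top `top_size` variants (by observed fitness)
#' contained in that set. An optimal predictor achieves recall 1 at
#' `budget == top_size`. Ties are broken deterministically by a stable
#' sort on (score decreasing, variant id increasing).
#'
#' @param predicted,observed Aligned numeric vectors.
#' @param budget Design budget N (number of top predictions kept).
#' @param top_size Size of the true top set (default 100).
#' @param ids Optional character ids used for stable tie-breaking;
#'   defaults to the element index.
#' @return Recall in \[0, 1\].
#' @export
recall_at_budget <- function(predicted, observed, budget, top_size = 100,
                             ids = NULL) {
  n <- length(predicted)
  stopifnot(length(observed) == n, top_size >= 1, top_size <= n, budget >= 1)
  if (is.null(ids)) ids <- formatC(seq_len(n), width = nchar(n), flag = "0")
  if (budget > n) {
    warning("budget ", budget, " exceeds population size ", n, "; clamped")
    budget <- n
  }
  model_top <- ids[order(-predicted, ids)][seq_len(budget)]
  true_top <- ids[order(-observed, ids)][seq_len(top_size)]
  length(intersect(model_top, true_top)) / top_size
}

#' Recall curve over several budgets
#'
#' @param predicted,observed Aligned numeric vectors.
#' @param budgets Integer vector of design budgets.
#' @param top_size Size of the true top set (default 100).
#' @param ids Optional stable-tie-break ids (see [recall_at_budget()]).
#' @return Data frame with columns `budget`, `recall`; recall is
#'   non-decreasing in the budget.
#' @export
recall_curve <- function(predicted, observed, budgets, top_size = 100,
                         ids = NULL) {
  data.frame(budget = budgets,
             recall = vapply(budgets, function(b) {
               recall_at_budget(predicted, observed, b, top_size, ids)
             }, 0))
}

#' Random mutational trajectory from wild type
#'
#' Builds an ordered pathway of variants with increasing mutation count:
#' step i carries exactly i substitutions, each step adding one random
#' substitution at a previously unmutated position. Used to probe how
#' model predictions diverge when walking away from the training regime.
#'
#' @param wild_type Wild-type sequence.
#' @param max_mutations Length of the walk (final Hamming distance).
#' @param seed Integer seed.
#' @return Character vector of `max_mutations + 1` sequences starting at
#'   the wild type.
#' @export
mutational_trajectory <- function(wild_type, max_mutations, seed = 0) {
  wt <- seq_to_int(wild_type)
  L <- length(wt)
  stopifnot(max_mutations >= 1, max_mutations <= L)
  with_seed(seed, {
    pos <- sample.int(L, max_mutations)
    cur <- wt
    out <- character(max_mutations + 1L)
    out[1] <- wild_type
    for (i in seq_len(max_mutations)) {
      aa <- sample.int(19L, 1L)
      if (aa >= wt[pos[i]]) aa <- aa + 1L
      cur[pos[i]] <- aa
      out[i + 1L] <- int_to_seq(cur)
    }
  })
  out
}

# population standard deviation
pop_sd <- function(x) sqrt(mean((x - mean(x))^2))

#' Prediction divergence of a model collection along a trajectory
#'
#' Evaluates every model on every step of a mutational pathway and
#' summarizes the across-model dispersion per step. The median and
#' 5th-percentile rows correspond to what median/conservative ensemble
#' predictors would return along the trajectory, and the 5th-percentile
#' row is never above the median row.
#'
#' @param models List of >= 2 predictors sharing a sequence length.
#' @param trajectory Character vector of sequences (ordered pathway, e.g.
#'   from [mutational_trajectory()]).
#' @return List with `predictions` (models x steps matrix), `dispersion`
#'   (data frame: `step` 0-based, `n_mut`, `sd`, `iqr`), `median` and
#'   `p5` (numeric vectors along the trajectory).
#' @export
trajectory_divergence <- function(models, trajectory) {
  if (length(models) < 2L) stop("need at least two models")
  if (length(trajectory) < 1L) stop("empty trajectory")
  P <- member_predictions(models, trajectory)
  n_mut <- vapply(trajectory, hamming_distance, 0L, b = trajectory[1],
                  USE.NAMES = FALSE)
  list(predictions = P,
       dispersion = data.frame(step = seq_along(trajectory) - 1L,
                               n_mut = n_mut,
                               sd = apply(P, 2L, pop_sd),
                               iqr = apply(P, 2L, stats::IQR)),
       median = apply(P, 2L, median),
       p5 = apply(P, 2L, quantile, probs = 0.05, type = 1, names = FALSE))
}

#' Per-sequence disagreement across a model collection
#'
#' @param models List of >= 2 predictors (or a [fitness_ensemble()]).
#' @param seqs Character vector of sequences.
#' @return Data frame with per-sequence `sd` (population), `iqr`, `min`,
#'   `max` over member predictions.
#' @export
ensemble_disagreement <- function(models, seqs) {
  members <- if (inherits(models, "fitness_ensemble")) models$members else models
  if (length(members) < 2L) stop("need at least two models")
  P <- member_predictions(members, seqs)
  data.frame(sequence = seqs,
             sd = apply(P, 2L, pop_sd),
             iqr = apply(P, 2L, stats::IQR),
             min = apply(P, 2L, min),
             max = apply(P, 2L, max),
             stringsAsFactors = FALSE)
}
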