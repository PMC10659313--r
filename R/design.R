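#' Simulated-annealing configuration for fixed-distance design
#'
#' Parameters of a design run that searches sequence space at a fixed
#' Hamming distance `k` from wild type. The temperature follows a
#' logarithmic (geometric) gradient from `t_start` to `t_end`; the move
#' size (number of mutations exchanged per step) is zero-truncated
#' Poisson(`lambda`).
#'
#' @param k Target mutation count (>= 1).
#' @param n_steps Number of SA steps (>= 2; the field default regime is
#'   15,000-50,000, see [default_sa_steps()]).
#' @param t_start,t_end Temperature endpoints (defaults 1e3 and 1e-5).
#' @param lambda Poisson mean of the exchange move size (default 1).
#' @param seed Integer seed making the run reproducible.
#' @return Object of class `anneal_config`.
#' @export
anneal_config <- function(k, n_steps = 20000, t_start = 1e3, t_end = 1e-5,
                          lambda = 1, seed = 0) {
  k <- as.integer(k)
  n_steps <- as.integer(n_steps)
  if (k < 1L) stop("k must be >= 1")
  if (n_steps < 2L) stop("n_steps must be >= 2")
  if (!(t_start > t_end && t_end > 0)) stop("need t_start > t_end > 0")
  if (lambda <= 0) stop("lambda must be positive")
  structure(list(k = k, n_steps = n_steps, t_start = t_start, t_end = t_end,
                 lambda = lambda, seed = seed),
            class = "anneal_config")
}

#' Default SA step counts per model/distance combination
#'
#' Smooth, strongly convergent model-distance combinations need fewer
#' steps so that independent runs do not all collapse onto one sequence:
#' 10,000 steps for (linear, 5) and (fcn, 5); 25,000 for (linear, 10),
#' (fcn, 10), (ensm, 5) and (ensc, 5); 50,000 otherwise.
#'
#' @param model_tag Model label (e.g. `"linear"`, `"fcn"`, `"cnn0"`,
#'   `"gcn"`, `"ensm"`, `"ensc"`). CNN tags of the form `cnn<i>` are
#'   treated as `"cnn"`.
#' @param k Mutation distance.
#' @return Integer step count.
#' @export
default_sa_steps <- function(model_tag, k) {
  tag <- sub("^(lr|linear)$", "linear", tolower(model_tag))
  if (tag %in% c("linear", "fcn") && k == 5) return(10000L)
  if ((tag %in% c("linear", "fcn") && k == 10) ||
      (tag %in% c("ensm", "ensc") && k == 5)) return(25000L)
  50000L
}

#' Logarithmic temperature schedule
#'
#' Geometric interpolation between the temperature endpoints:
#' `T(step) = 10^(log10 t_start + (log10 t_end - log10 t_start) *
#' step/(n_steps-1))` for 0-based `step`; monotone decreasing.
#'
#' @param step 0-based step index (vectorized), `0 <= step < n_steps`.
#' @param n_steps Total steps.
#' @param t_start,t_end Temperature endpoints.
#' @return Temperature(s).
#' @examples
#' temperature_schedule(0, 15000)        # 1000
#' temperature_schedule(14999, 15000)    # 1e-5
#' @export
temperature_schedule <- function(step, n_steps, t_start = 1e3, t_end = 1e-5) {
  if (any(step < 0 | step >= n_steps)) stop("step out of range [0, n_steps)")
  10^(log10(t_start) +
        (log10(t_end) - log10(t_start)) * step / (n_steps - 1))
}

#' Zero-truncated Poisson draws
#'
#' Samples from Poisson(`lambda`) conditioned on being positive, by
#' rejection of zero draws ("one or more mutations" per exchange move).
#' The mean is `lambda / (1 - exp(-lambda))` (~1.582 for `lambda = 1`).
#'
#' @param n Number of draws.
#' @param lambda Poisson mean before truncation.
#' @return Integer vector of positive draws.
#' @export
rztpois <- function(n, lambda = 1) {
  x <- rpois(n, lambda)
  while (any(x == 0L)) {
    zero <- x == 0L
    x[zero] <- rpois(sum(zero), lambda)
  }
  x
}

# Exchange move on integer-encoded sequences. cur/wt are length-L integer
# vectors; exactly k positions of cur differ from wt on entry and exit.
# Draws m ~ zero-truncated Poisson(lambda) (clamped to k), reverts m random
# current mutations, then introduces m new mutations at positions that are
# wild type after the reversion (just-reverted positions are eligible),
# with amino acids uniform over the 19 non-wild-type residues.
propose_exchange_int <- function(cur, wt, lambda = 1) {
  mutated <- which(cur != wt)
  k <- length(mutated)
  m <- min(rztpois(1L, lambda), k)
  revert <- mutated[sample.int(k, m)]
  prop <- cur
  prop[revert] <- wt[revert]
  free <- which(prop == wt)
  new_pos <- free[sample.int(length(free), m)]
  for (p in new_pos) {
    aa <- sample.int(19L, 1L)
    if (aa >= wt[p]) aa <- aa + 1L  # skip the wild-type residue
    prop[p] <- aa
  }
  prop
}

#' Distance-preserving exchange move
#'
#' Proposes a new variant at the same Hamming distance from wild type as
#' the current one: a zero-truncated Poisson(`lambda`) number of existing
#' substitutions are reverted and the same number of new substitutions are
#' introduced at random wild-type positions (reverted positions included),
#' with amino acids uniform over the 19 non-wild-type residues. Uses the
#' ambient RNG.
#'
#' @param current A [protein_variant()] (with at least one substitution).
#' @param lambda Poisson mean of the move size (default 1).
#' @return A [protein_variant()] with the same number of substitutions.
#' @export
propose_exchange <- function(current, lambda = 1) {
  stopifnot(inherits(current, "protein_variant"))
  if (length(current$pos) < 1L) stop("current variant carries no mutations")
  wt <- seq_to_int(current$wild_type)
  if (length(current$pos) > length(wt)) stop("k exceeds sequence length")
  cur <- seq_to_int(variant_sequence(current))
  prop <- propose_exchange_int(cur, wt, lambda)
  d <- which(prop != wt)
  protein_variant(current$wild_type, pos = d - 1L, aa = AA_ALPHABET[prop[d]])
}

# Random k-mutant used to initialize a chain (ambient RNG).
random_k_mutant_int <- function(wt, k) {
  pos <- sample.int(length(wt), k)
  cur <- wt
  for (p in pos) {
    aa <- sample.int(19L, 1L)
    if (aa >= wt[p]) aa <- aa + 1L
    cur[p] <- aa
  }
  cur
}

#' Simulated-annealing design at fixed mutation distance
#'
#' Maximizes a model's predicted fitness over the space of `k`-mutants of
#' the wild type. Every state of the chain has Hamming distance exactly
#' `k` from wild type (exchange moves preserve distance). Moves that
#' improve predicted fitness are always accepted; all others are accepted
#' with probability `exp(dFitness / T)` under the logarithmic temperature
#' schedule. Returns the best variant observed during the run (not
#' necessarily the final state, which may sit in a late downhill
#' excursion).
#'
#' @param model A `fitness_model`, [fitness_ensemble()], or any object
#'   with a `predict(object, sequences)` method returning finite reals.
#' @param wild_type Wild-type sequence.
#' @param config An [anneal_config()].
#' @param trace If `TRUE`, record a per-step trace (step, temperature,
#'   accepted flag, current and best fitness).
#' @return Object of class `design_run`: fields `variant`
#'   ([protein_variant()]), `fitness` (best predicted fitness), `k`,
#'   `seed`, and optionally `trace`.
#' @export
sa_design <- function(model, wild_type, config, trace = FALSE) {
  stopifnot(inherits(config, "anneal_config"))
  wt <- seq_to_int(wild_type)
  L <- length(wt)
  if (config$k > L) stop("k (", config$k, ") exceeds sequence length ", L)
  temps <- temperature_schedule(seq_len(config$n_steps) - 1L, config$n_steps,
                                config$t_start, config$t_end)
  tr <- if (trace) {
    data.frame(step = seq_len(config$n_steps), temperature = temps,
               accepted = NA, fitness = NA_real_, best_fitness = NA_real_,
               distance = NA_integer_)
  }
  with_seed(config$seed, {
    cur <- random_k_mutant_int(wt, config$k)
    cur_fit <- predict(model, int_to_seq(cur))
    if (!is.finite(cur_fit)) {
      stop("non-finite model prediction at initialization (seed ",
           config$seed, ")")
    }
    best <- cur
    best_fit <- cur_fit
    for (step in seq_len(config$n_steps)) {
      prop <- propose_exchange_int(cur, wt, config$lambda)
      u <- runif(1L)  # drawn unconditionally to keep RNG use per step fixed
      prop_fit <- predict(model, int_to_seq(prop))
      if (!is.finite(prop_fit)) {
        stop("non-finite model prediction at step ", step,
             " (seed ", config$seed, ")")
      }
      dfit <- prop_fit - cur_fit
      if (dfit > 0 || u < exp(dfit / temps[step])) {
        cur <- prop
        cur_fit <- prop_fit
        if (cur_fit > best_fit) {
          best <- cur
          best_fit <- cur_fit
        }
        accepted <- TRUE
      } else {
        accepted <- FALSE
      }
      if (trace) {
        tr$accepted[step] <- accepted
        tr$fitness[step] <- cur_fit
        tr$best_fitness[step] <- best_fit
        tr$distance[step] <- sum(cur != wt)
      }
    }
  })
  d <- which(best != wt)
  structure(list(variant = protein_variant(wild_type, pos = d - 1L,
                                           aa = AA_ALPHABET[best[d]]),
                 fitness = best_fit, k = config$k, seed = config$seed,
                 trace = tr),
            class = "design_run")
}

#' @export
print.design_run <- function(x, ...) {
  cat("<design_run> k=", x$k, ", predicted fitness ",
      signif(x$fitness, 5), ": ", mutation_string(x$variant), "\n", sep = "")
  invisible(x)
}

#' Multi-run simulated-annealing design campaign
#'
#' Executes `n_runs` independent SA chains (run r uses seed
#' `base_seed + r - 1`), identical to calling [sa_design()] once per seed.
#' Internally the chains advance in lockstep with per-run RNG streams so
#' model predictions can be batched across runs, which is substantially
#' faster for ensemble and convolutional models; results are identical to
#' serial execution.
#'
#' @param model Predictor (see [sa_design()]).
#' @param wild_type Wild-type sequence.
#' @param config An [anneal_config()]; its `seed` field is ignored in
#'   favor of `base_seed + run index`.
#' @param n_runs Number of independent runs (full-scale default 500).
#' @param base_seed Seed of the first run.
#' @return Object of class `design_campaign`: list of `design_run`s with
#'   attributes `k`, `n_steps` and `base_seed`.
#' @export
run_campaign <- function(model, wild_type, config, n_runs = 500,
                         base_seed = 0) {
  stopifnot(inherits(config, "anneal_config"), n_runs >= 1)
  wt <- seq_to_int(wild_type)
  L <- length(wt)
  if (config$k > L) stop("k (", config$k, ") exceeds sequence length ", L)
  n_runs <- as.integer(n_runs)
  temps <- temperature_schedule(seq_len(config$n_steps) - 1L, config$n_steps,
                                config$t_start, config$t_end)
  old_rng <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_rng)) assign(".Random.seed", old_rng, envir = globalenv())
  })

  states <- vector("list", n_runs)
  cur <- matrix(0L, n_runs, L)
  for (r in seq_len(n_runs)) {
    set.seed(base_seed + r - 1L)
    cur[r, ] <- random_k_mutant_int(wt, config$k)
    states[[r]] <- get(".Random.seed", envir = globalenv())
  }
  cur_fit <- predict(model, int_matrix_to_seqs(cur))
  if (any(!is.finite(cur_fit))) stop("non-finite model prediction at init")
  best <- cur
  best_fit <- cur_fit
  u <- numeric(n_runs)
  prop <- cur
  for (step in seq_len(config$n_steps)) {
    for (r in seq_len(n_runs)) {
      assign(".Random.seed", states[[r]], envir = globalenv())
      prop[r, ] <- propose_exchange_int(cur[r, ], wt, config$lambda)
      u[r] <- runif(1L)
      states[[r]] <- get(".Random.seed", envir = globalenv())
    }
    prop_fit <- predict(model, int_matrix_to_seqs(prop))
    if (any(!is.finite(prop_fit))) {
      stop("non-finite model prediction at step ", step)
    }
    dfit <- prop_fit - cur_fit
    acc <- dfit > 0 | u < exp(dfit / temps[step])
    if (any(acc)) {
      cur[acc, ] <- prop[acc, , drop = FALSE]
      cur_fit[acc] <- prop_fit[acc]
      improved <- acc & cur_fit > best_fit
      if (any(improved)) {
        best[improved, ] <- cur[improved, , drop = FALSE]
        best_fit[improved] <- cur_fit[improved]
      }
    }
  }
  runs <- lapply(seq_len(n_runs), function(r) {
    d <- which(best[r, ] != wt)
    structure(list(variant = protein_variant(wild_type, pos = d - 1L,
                                             aa = AA_ALPHABET[best[r, d]]),
                   fitness = best_fit[r], k = config$k,
                   seed = base_seed + r - 1L, trace = NULL),
              class = "design_run")
  })
  structure(runs, class = "design_campaign", k = config$k,
            n_steps = config$n_steps, base_seed = base_seed)
}

# k-means++ seeding: distinct rows of x as initial centers.
kmeanspp_centers <- function(x, k) {
  n <- nrow(x)
  centers <- integer(k)
  centers[1] <- sample.int(n, 1L)
  d2 <- rowSums(sweep(x, 2L, x[centers[1], ], `-`)^2)
  for (j in seq_len(k - 1L)) {
    probs <- d2 / sum(d2)
    centers[j + 1L] <- sample.int(n, 1L, prob = probs)
    d2_new <- rowSums(sweep(x, 2L, x[centers[j + 1L], ], `-`)^2)
    d2 <- pmin(d2, d2_new)
  }
  centers
}

#' Select diverse design representatives by clustering
#'
#' Deduplicates the final designs of a campaign, K-means-clusters the
#' unique sequences (one-hot encoding, Euclidean metric, k-means++
#' seeding, 10 restarts, fixed seed) into `n_clusters` clusters, and
#' returns from each cluster the member with the highest predicted
#' fitness. This yields exactly `n_clusters` unique sequences spread over
#' the distinct fitness peaks the campaign discovered.
#'
#' @param runs A `design_campaign` (or list of `design_run`s).
#' @param n_clusters Number of clusters/representatives (default 41).
#' @param seed Clustering seed (default 0).
#' @param nstart Number of k-means restarts (default 10).
#' @return Data frame with columns `sequence`, `variant` (mutation
#'   string), `fitness`, `cluster`, `run_seed`, one row per cluster,
#'   sorted by decreasing fitness.
#' @export
select_representatives <- function(runs, n_clusters = 41, seed = 0,
                                   nstart = 10) {
  stopifnot(length(runs) >= 1L)
  seqs <- vapply(runs, function(r) variant_sequence(r$variant), "")
  fits <- vapply(runs, function(r) r$fitness, 0)
  seeds <- vapply(runs, function(r) r$seed, 0)
  first <- !duplicated(seqs)
  useq <- seqs[first]
  ufit <- fits[first]
  useed <- seeds[first]
  n_unique <- length(useq)
  if (n_unique < n_clusters) {
    stop("only ", n_unique, " unique designs for ", n_clusters,
         " clusters; rerun the campaign with fewer SA steps (earlier ",
         "stopping preserves more distinct solutions) or more runs")
  }
  if (n_unique == n_clusters) {
    # one design per cluster: clustering is the identity
    cl <- list(cluster = seq_len(n_unique))
  } else {
  X <- encode_sequences(useq)
  cl <- with_seed(seed, {
    best_fit <- NULL
    for (s in seq_len(nstart)) {
      init <- X[kmeanspp_centers(X, n_clusters), , drop = FALSE]
      km <- suppressWarnings(kmeans(X, centers = init, iter.max = 50L))
      if (length(unique(km$cluster)) < n_clusters) next  # empty cluster
      if (is.null(best_fit) || km$tot.withinss < best_fit$tot.withinss) {
        best_fit <- km
      }
    }
    if (is.null(best_fit)) {
      stop("k-means failed to produce ", n_clusters, " non-empty clusters")
    }
    best_fit
  })
  }
  wt <- runs[[1]]$variant$wild_type
  pick <- vapply(seq_len(n_clusters), function(g) {
    members <- which(cl$cluster == g)
    members[order(-ufit[members], useq[members])][1]
  }, 1L)
  out <- data.frame(sequence = useq[pick],
                    variant = mutation_strings_from_seqs(useq[pick], wt),
                    fitness = ufit[pick],
                    cluster = seq_len(n_clusters),
                    run_seed = useed[pick],
                    stringsAsFactors = FALSE)
  out <- out[order(-out$fitness, out$sequence), , drop = FALSE]
  attr(out, "assignment") <- data.frame(sequence = useq, fitness = ufit,
                                        cluster = cl$cluster,
                                        stringsAsFactors = FALSE)
  out
}

#' Run the full model-by-distance design grid
#'
#' Orchestrates the complete design pipeline over a set of predictors and
#' mutation distances: for every (model, distance) combination it runs an
#' independent SA campaign, clusters the unique designs, and keeps the
#' per-cluster fittest representatives. With M models, D distances and C
#' clusters the grid yields exactly M x D x C designs.
#'
#' @param models Named list of predictors (models and/or ensembles); the
#'   names become the model tags of the output.
#' @param wild_type Wild-type sequence.
#' @param distances Integer vector of target mutation counts.
#' @param n_runs SA runs per combination (full-scale default 500).
#' @param n_steps SA steps per run; a single value, or `NULL` to use
#'   [default_sa_steps()] per combination.
#' @param n_clusters Representatives per combination (default 41).
#' @param base_seed Campaign seed; each combination derives its own run
#'   seeds from it deterministically.
#' @return List of campaigns (elements `model`, `k`, `representatives`,
#'   `n_unique`), ready for [write_design_manifest()].
#' @export
design_campaign_grid <- function(models, wild_type, distances,
                                 n_runs = 500, n_steps = NULL,
                                 n_clusters = 41, base_seed = 0) {
  stopifnot(is.list(models), !is.null(names(models)))
  out <- list()
  combo <- 0L
  for (nm in names(models)) {
    for (k in distances) {
      combo <- combo + 1L
      steps <- if (is.null(n_steps)) default_sa_steps(nm, k) else n_steps
      cfg <- anneal_config(k = k, n_steps = steps)
      camp <- run_campaign(models[[nm]], wild_type, cfg, n_runs = n_runs,
                           base_seed = base_seed + (combo - 1L) * n_runs)
      reps <- select_representatives(camp, n_clusters = n_clusters)
      out[[length(out) + 1L]] <- list(
        model = nm, k = k, representatives = reps,
        n_unique = length(unique(vapply(camp, function(r)
          variant_sequence(r$variant), ""))))
    }
  }
  out
}
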