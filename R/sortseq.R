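#' Sorted-population read-count table
#'
#' Container for per-design integer read counts across sorted populations:
#' `u` (unsorted), `d` (display only), `b` (binding), and optionally
#' `l`/`w`/`h` (low / wild-type-like / high binding) from a quantitative
#' sort. Carries the wild-type design id and the FACS population
#' proportions `(w_b, w_d)` used by the display score (these are
#' experiment-specific sort fractions, not constants).
#'
#' @param counts Data frame with a `design_id` column and integer count
#'   columns named among `u`, `d`, `b`, `l`, `w`, `h` (`u` required).
#' @param wt_id Design id of the wild type (must be present).
#' @param w_b,w_d Relative proportions of the binding and display-only
#'   populations from the sort (defaults 0.6 and 0.4; must sum to 1).
#' @return Object of class `sortseq_counts` (a data frame with
#'   attributes `wt_id`, `w_b`, `w_d`).
#' @export
sortseq_counts <- function(counts, wt_id, w_b = 0.6, w_d = 0.4) {
  stopifnot(is.data.frame(counts), "design_id" %in% names(counts),
            "u" %in% names(counts))
  pops <- intersect(c("u", "d", "b", "l", "w", "h"), names(counts))
  for (p in pops) {
    if (any(counts[[p]] < 0) || any(counts[[p]] != round(counts[[p]]))) {
      stop("counts in population '", p, "' must be non-negative integers")
    }
  }
  if (!wt_id %in% counts$design_id) stop("wild-type id '", wt_id,
                                         "' not present")
  if (anyDuplicated(counts$design_id)) stop("duplicate design ids")
  if (abs(w_b + w_d - 1) > 1e-8) stop("w_b + w_d must equal 1")
  structure(counts, class = c("sortseq_counts", "data.frame"),
            wt_id = wt_id, w_b = w_b, w_d = w_d)
}

#' Simulate sort-seq read counts from known display/binding probabilities
#'
#' Generates multinomial read counts for the unsorted, display-only and
#' binding populations of a sorted yeast-display library. Cell routing
#' follows the screen's logic: unsorted reads are proportional to input
#' abundance; display-only reads to abundance x display x (1 - bind);
#' binding reads to abundance x display x bind. Each population is
#' sequenced to exactly `depth` reads.
#'
#' @param design_ids Character vector of design ids (unique).
#' @param display_prob,bind_prob Per-design probabilities in \[0, 1\].
#' @param depth Reads per population (> 0).
#' @param seed Integer seed.
#' @param abundance Optional input abundances (default uniform).
#' @param wt_id Wild-type id (default the first design).
#' @param w_b,w_d Sort-fraction weights stored on the result.
#' @return A [sortseq_counts()] object.
#' @export
simulate_sortseq_counts <- function(design_ids, display_prob, bind_prob,
                                    depth = 1e6, seed = 1,
                                    abundance = NULL,
                                    wt_id = design_ids[1],
                                    w_b = 0.6, w_d = 0.4) {
  n <- length(design_ids)
  stopifnot(length(display_prob) == n, length(bind_prob) == n, depth > 0,
            all(display_prob >= 0 & display_prob <= 1),
            all(bind_prob >= 0 & bind_prob <= 1))
  if (is.null(abundance)) abundance <- rep(1, n)
  draw <- function(w) {
    if (sum(w) <= 0) return(rep(0L, n))
    as.integer(rmultinom(1L, size = depth, prob = w / sum(w)))
  }
  with_seed(seed, {
    u <- draw(abundance)
    d <- draw(abundance * display_prob * (1 - bind_prob))
    b <- draw(abundance * display_prob * bind_prob)
  })
  sortseq_counts(data.frame(design_id = design_ids, u = u, d = d, b = b,
                            stringsAsFactors = FALSE),
                 wt_id = wt_id, w_b = w_b, w_d = w_d)
}

#' Merge a forward/reverse read pair by quality
#'
#' Places the (already reverse-complemented) reverse read at a
#' predetermined offset relative to the forward read and merges: bases
#' covered by one read are copied verbatim; in the overlap the base with
#' the higher Phred quality wins, with ties going to the forward read.
#'
#' @param fwd,rev Read sequences (single strings); `rev` must already be
#'   reverse-complemented into forward orientation.
#' @param fwd_qual,rev_qual Phred+33-encoded quality strings, or integer
#'   Phred vectors, aligned with the reads.
#' @param offset 0-based start of the reverse read relative to the
#'   forward read's start. `offset == nchar(fwd)` concatenates;
#'   `offset > nchar(fwd)` (a gap) or `offset < 0` is an error.
#' @return Merged nucleotide sequence (single string).
#' @export
merge_read_pair <- function(fwd, fwd_qual, rev, rev_qual, offset) {
  phred <- function(q, len) {
    if (is.character(q)) q <- utf8ToInt(q) - 33L
    stopifnot(length(q) == len)
    q
  }
  lf <- nchar(fwd)
  lr <- nchar(rev)
  qf <- phred(fwd_qual, lf)
  qr <- phred(rev_qual, lr)
  if (offset < 0) stop("negative offset: reverse read before forward start")
  if (offset > lf) stop("offset leaves a gap between the reads")
  total <- max(lf, offset + lr)
  base <- character(total)
  qual <- rep(-1L, total)
  fc <- strsplit(fwd, "", fixed = TRUE)[[1]]
  rc <- strsplit(rev, "", fixed = TRUE)[[1]]
  base[seq_len(lf)] <- fc
  qual[seq_len(lf)] <- qf
  rpos <- offset + seq_len(lr)
  win <- qr > qual[rpos]  # strict: ties keep the forward base
  base[rpos[win]] <- rc[win]
  qual[rpos[win]] <- qr[win]
  paste(base, collapse = "")
}

#' Count reads exactly matching designed nucleotide sequences
#'
#' A design's count is the number of reads whose sequence is exactly
#' identical to the designed nucleotide sequence; anything else (even one
#' mismatch) is tallied as unassigned. Synonymous control constructs must
#' be registered under distinct ids with distinct nucleotide sequences.
#'
#' @param reads Character vector of (merged) read sequences.
#' @param design_library Named character vector mapping design id to its
#'   nucleotide sequence; sequences must be unique across ids.
#' @return Named integer vector of counts per design id, with an
#'   `unassigned` attribute giving the number of unmatched reads.
#' @export
count_exact_matches <- function(reads, design_library) {
  if (is.null(names(design_library)) || any(names(design_library) == "")) {
    stop("design_library must be named by design id")
  }
  if (anyDuplicated(design_library)) {
    stop("duplicate nucleotide sequences across design ids")
  }
  hit <- match(reads, design_library)
  counts <- tabulate(hit, nbins = length(design_library))
  names(counts) <- names(design_library)
  attr(counts, "unassigned") <- sum(is.na(hit))
  counts
}

#' Filter designs by unsorted read count
#'
#' Removes designs with fewer than `min_count` reads in the unsorted
#' population (poorly represented designs whose enrichment estimates
#' would be dominated by counting noise). The wild type is the scoring
#' reference and may never be removed: a wild type below threshold is a
#' hard error.
#'
#' @param counts A [sortseq_counts()] object.
#' @param min_count Minimum unsorted count (default 10).
#' @return Filtered [sortseq_counts()].
#' @export
filter_min_count <- function(counts, min_count = 10) {
  stopifnot(inherits(counts, "sortseq_counts"))
  wt_id <- attr(counts, "wt_id")
  wt_u <- counts$u[counts$design_id == wt_id]
  if (wt_u < min_count) {
    stop("wild type has only ", wt_u, " unsorted reads (< ", min_count, ")")
  }
  keep <- counts$u >= min_count
  sortseq_counts(as.data.frame(counts)[keep, , drop = FALSE],
                 wt_id = wt_id,
                 w_b = attr(counts, "w_b"), w_d = attr(counts, "w_d"))
}

# per-population proportions from a count data frame
pop_proportions <- function(df, pops) {
  out <- lapply(pops, function(p) df[[p]] / sum(df[[p]]))
  names(out) <- pops
  out
}

#' Display and binding enrichment scores
#'
#' Computes, per design i with population proportions p (counts divided
#' by the population's total reads):
#'
#' * binding score: `e_bind = log10(p_b,i / p_d,i) - log10(p_b,wt / p_d,wt)`
#'   (enrichment in the binding population relative to display-only);
#' * display score: `e_disp = log10((w_b p_b,i + w_d p_d,i) / p_u,i) -
#'   log10((w_b p_b,wt + w_d p_d,wt) / p_u,wt)` where the numerator
#'   reconstructs the full displaying population from the two sorted
#'   populations using the FACS sort proportions `(w_b, w_d)`.
#'
#' Wild-type rows score exactly 0 by construction. Designs with a zero
#' count in `b` or `d` receive a +1 pseudocount in both populations
#' (flagged in the output) so their scores stay finite without shifting
#' the wild-type normalization.
#'
#' @param counts A (filtered) [sortseq_counts()] with `u`, `d`, `b`.
#' @return Data frame of class `enrichment_table` with columns
#'   `design_id`, `e_bind`, `e_disp`, `pseudocount`.
#' @export
enrichment_scores <- function(counts) {
  stopifnot(inherits(counts, "sortseq_counts"),
            all(c("u", "d", "b") %in% names(counts)))
  wt_id <- attr(counts, "wt_id")
  w_b <- attr(counts, "w_b")
  w_d <- attr(counts, "w_d")
  df <- as.data.frame(counts)
  wt_row <- which(df$design_id == wt_id)
  if (df$b[wt_row] == 0 || df$d[wt_row] == 0 || df$u[wt_row] == 0) {
    stop("wild type must have nonzero counts in u, d and b")
  }
  pseudo <- df$b == 0 | df$d == 0
  df$b[pseudo] <- df$b[pseudo] + 1L
  df$d[pseudo] <- df$d[pseudo] + 1L
  p <- pop_proportions(df, c("u", "d", "b"))
  bind_ratio <- log10(p$b / p$d)
  disp_ratio <- log10((w_b * p$b + w_d * p$d) / p$u)
  out <- data.frame(design_id = df$design_id,
                    e_bind = bind_ratio - bind_ratio[wt_row],
                    e_disp = disp_ratio - disp_ratio[wt_row],
                    pseudocount = pseudo,
                    stringsAsFactors = FALSE)
  structure(out, class = c("enrichment_table", "data.frame"), wt_id = wt_id)
}

#' Enrichment of a single sorted population over the unsorted pool
#'
#' For a quantitative sort into populations x in {l, w, h} (or d/b),
#' computes `e_x = log10(p_x,i / p_u,i) - log10(p_x,wt / p_u,wt)`; the
#' wild type scores exactly 0.
#'
#' @param counts A [sortseq_counts()] containing the requested population.
#' @param population One of `"l"`, `"w"`, `"h"`, `"d"`, `"b"`.
#' @return Data frame with `design_id`, `e_x`, `pseudocount` flag.
#' @export
population_enrichment <- function(counts, population) {
  stopifnot(inherits(counts, "sortseq_counts"))
  population <- match.arg(population, c("l", "w", "h", "d", "b"))
  if (!population %in% names(counts)) {
    stop("population '", population, "' not present in the count table")
  }
  wt_id <- attr(counts, "wt_id")
  df <- as.data.frame(counts)
  wt_row <- which(df$design_id == wt_id)
  if (df[[population]][wt_row] == 0 || df$u[wt_row] == 0) {
    stop("wild type must have nonzero counts in u and '", population, "'")
  }
  pseudo <- df[[population]] == 0
  df[[population]][pseudo] <- df[[population]][pseudo] + 1L
  df$u[pseudo] <- df$u[pseudo] + 1L
  p <- pop_proportions(df, c("u", population))
  ratio <- log10(p[[population]] / p$u)
  data.frame(design_id = df$design_id,
             e_x = ratio - ratio[wt_row],
             pseudocount = pseudo,
             stringsAsFactors = FALSE)
}

#' Classify designs into display/binding quadrants
#'
#' Assigns each design a quadrant from its display and binding scores:
#' scores at or above the threshold count as positive (so a wild type
#' with thresholds at 0 is classified as displaying and binding).
#'
#' @param table An [enrichment_scores()] table.
#' @param thresholds List with elements `display` and `bind` (score
#'   cutoffs), or `NULL` to derive both from `calibration`.
#' @param calibration Optional data frame with columns `e_disp`, `e_bind`
#'   and logical columns `displays`, `binds` for constructs of known
#'   phenotype; each threshold is the midpoint between the positive and
#'   negative group means.
#' @return The table with a `category` factor column added (levels
#'   `display_bind`, `display_only`, `bind_no_display`, `inactive`).
#' @export
classify_designs <- function(table, thresholds = NULL, calibration = NULL) {
  stopifnot(inherits(table, "enrichment_table"))
  if (is.null(thresholds)) {
    if (is.null(calibration)) {
      stop("supply thresholds or calibration records")
    }
    thresholds <- list(
      display = midpoint_threshold(calibration$e_disp, calibration$displays),
      bind = midpoint_threshold(calibration$e_bind, calibration$binds))
  }
  disp <- table$e_disp >= thresholds$display
  bind <- table$e_bind >= thresholds$bind
  table$category <- factor(ifelse(disp & bind, "display_bind",
                           ifelse(disp, "display_only",
                           ifelse(bind, "bind_no_display", "inactive"))),
                           levels = c("display_bind", "display_only",
                                      "bind_no_display", "inactive"))
  table
}

# midpoint between the means of the positive and negative calibration groups
midpoint_threshold <- function(values, positive) {
  stopifnot(any(positive), any(!positive))
  (mean(values[positive]) + mean(values[!positive])) / 2
}

#' Calibration-derived bin boundaries
#'
#' Derives classification boundaries from calibration constructs with
#' known class labels: classes are ordered by their mean score and each
#' boundary is the midpoint between the means of adjacent classes.
#'
#' @param values Numeric scores of the calibration constructs.
#' @param classes Class labels (factor or character), >= 2 classes.
#' @return Named numeric vector of boundaries (one fewer than classes),
#'   with a `classes` attribute giving the mean-ordered class labels.
#' @export
calibration_thresholds <- function(values, classes) {
  means <- vapply(split(values, classes), mean, 0)
  means <- sort(means)
  if (length(means) < 2L) stop("need at least two calibration classes")
  bounds <- (means[-1] + means[-length(means)]) / 2
  names(bounds) <- paste(names(means)[-length(means)], names(means)[-1],
                         sep = "|")
  attr(bounds, "classes") <- names(means)
  bounds
}

#' Classify scores against calibration-derived boundaries
#'
#' @param values Numeric scores.
#' @param boundaries Output of [calibration_thresholds()].
#' @return Factor of class labels (boundaries are assigned upward: a value
#'   equal to a boundary falls into the higher class).
#' @export
classify_bins <- function(values, boundaries) {
  classes <- attr(boundaries, "classes")
  idx <- findInterval(values, boundaries, left.open = TRUE) + 1L
  factor(classes[idx], levels = classes)
}

#' Fit a saturation binding (Hill) curve
#'
#' Least-squares fit of `signal = bmax * c / (kd + c)` (Hill coefficient
#' fixed at 1) to titration data, estimating the dissociation constant KD
#' and the maximum binding signal. Degenerate all-zero signals yield
#' `bmax = 0` with KD flagged as undetermined.
#'
#' @param concentrations Ligand concentrations (>= 3 points, same units
#'   as the reported KD).
#' @param signals Non-negative binding signals aligned with
#'   `concentrations`.
#' @return List of class `hill_fit`: `kd`, `bmax`, `residual_norm`,
#'   `fitted`, `degenerate` flag.
#' @export
fit_hill <- function(concentrations, signals) {
  stopifnot(length(concentrations) == length(signals),
            length(signals) >= 3L)
  if (any(signals < 0)) stop("signals must be non-negative")
  if (all(signals == 0)) {
    return(structure(list(kd = NA_real_, bmax = 0, residual_norm = 0,
                          fitted = rep(0, length(signals)),
                          degenerate = TRUE),
                     class = "hill_fit"))
  }
  bmax0 <- max(signals)
  half <- bmax0 / 2
  above <- which(signals >= half)
  kd0 <- if (length(above)) concentrations[above[1]] else median(concentrations)
  kd0 <- max(kd0, .Machine$double.eps)
  fit <- minpack.lm::nlsLM(
    s ~ bmax * conc / (kd + conc),
    data = data.frame(s = signals, conc = concentrations),
    start = list(bmax = bmax0, kd = kd0),
    lower = c(bmax = 0, kd = 0),
    control = minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-14,
                                         ptol = 1e-14))
  est <- coef(fit)
  structure(list(kd = unname(est["kd"]), bmax = unname(est["bmax"]),
                 residual_norm = sqrt(sum(resid(fit)^2)),
                 fitted = fitted(fit), degenerate = FALSE),
            class = "hill_fit")
}

#' @export
print.hill_fit <- function(x, ...) {
  if (x$degenerate) {
    cat("<hill_fit> degenerate (all-zero signals): bmax = 0, KD undetermined\n")
  } else {
    cat("<hill_fit> KD = ", signif(x$kd, 5), ", bmax = ", signif(x$bmax, 5),
        ", residual norm ", signif(x$residual_norm, 4), "\n", sep = "")
  }
  invisible(x)
}
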