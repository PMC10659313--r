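#' Ensemble predictor over independently trained models
#'
#' Aggregates the predictions of several models trained with different
#' random initializations on the same data. Two aggregation modes mirror
#' the two standard ensemble strategies:
#'
#' * `"median"` — the member-wise median ("average" predictor, EnsM-style);
#' * `"percentile"` — the p-th percentile of member predictions with lower
#'   interpolation (inverse-ECDF, `type = 1`); with the default p = 5 this
#'   is a conservative predictor (EnsC-style): 95% of members predict a
#'   higher fitness than the value returned.
#'
#' For any input, the 5th-percentile aggregate is never above the median
#' aggregate (order statistics).
#'
#' @param members List of `fitness_model` objects sharing a sequence length.
#' @param aggregation `"median"` or `"percentile"`.
#' @param p Percentile in (0, 100) for `"percentile"` mode (default 5).
#' @param tag Optional label (e.g. `"ensm"`/`"ensc"`).
#' @return Object of class `fitness_ensemble` (also usable anywhere a
#'   predictor is accepted, e.g. in [sa_design()]).
#' @export
fitness_ensemble <- function(members, aggregation = c("median", "percentile"),
                             p = 5, tag = NULL) {
  aggregation <- match.arg(aggregation)
  if (length(members) < 1L) stop("ensemble needs at least one member")
  if (!all(vapply(members, inherits, TRUE, "fitness_model"))) {
    stop("all members must be fitness_model objects")
  }
  Ls <- vapply(members, function(m) m$spec$L, 1L)
  if (length(unique(Ls)) != 1L) stop("members must share sequence length")
  if (aggregation == "percentile" && (p <= 0 || p >= 100)) {
    stop("percentile p must be in (0, 100)")
  }
  if (is.null(tag)) {
    tag <- if (aggregation == "median") "ensm" else "ensc"
  }
  structure(list(members = members, aggregation = aggregation, p = p,
                 tag = tag,
                 spec = list(L = Ls[1], architecture = "ensemble")),
            class = "fitness_ensemble")
}

#' @export
print.fitness_ensemble <- function(x, ...) {
  cat("<fitness_ensemble> ", length(x$members), " members, ",
      if (x$aggregation == "median") "median" else paste0(x$p, "th percentile"),
      " aggregation\n", sep = "")
  invisible(x)
}

#' Member-wise prediction matrix of an ensemble
#'
#' @param ensemble A [fitness_ensemble()] (or plain list of models).
#' @param seqs Character vector of sequences.
#' @return Numeric matrix, members x sequences.
#' @export
member_predictions <- function(ensemble, seqs) {
  members <- if (inherits(ensemble, "fitness_ensemble")) {
    ensemble$members
  } else {
    ensemble
  }
  L <- members[[1]]$spec$L
  X <- encode_sequences(seqs, L = L)
  t(vapply(members, function(m) predict(m, X), numeric(nrow(X))))
}

#' @rdname fitness_ensemble
#' @param object A `fitness_ensemble`.
#' @param newdata Character vector of sequences or pre-encoded one-hot
#'   matrix.
#' @param ... Unused.
#' @export
predict.fitness_ensemble <- function(object, newdata, ...) {
  X <- if (is.character(newdata)) {
    encode_sequences(newdata, L = object$spec$L)
  } else {
    newdata
  }
  preds <- vapply(object$members, function(m) predict(m, X),
                  numeric(nrow(X)))
  preds <- matrix(preds, nrow = nrow(X))  # sequences x members
  if (object$aggregation == "median") {
    apply(preds, 1L, median)
  } else {
    apply(preds, 1L, quantile, probs = object$p / 100, type = 1,
          names = FALSE)
  }
}
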