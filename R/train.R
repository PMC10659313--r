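#' Train a fitness predictor
#'
#' Fits a model built by [build_model()] to a fitness dataset by mini-batch
#' Adam on mean squared error, with early stopping on validation loss. The
#' per-epoch train and validation losses are recorded (epoch 0 is the loss
#' at initialization) and the parameters returned are those of the best
#' validation epoch.
#'
#' @param model An untrained (or trained) `fitness_model`.
#' @param data Fitness dataset data frame with columns `sequence`, `score`
#'   and `split` (needs nonempty `"train"` and `"val"` splits; see
#'   [assign_splits()]).
#' @param epochs,learning_rate,batch_size,patience Training hyperparameters;
#'   default to the values stored in the model's spec.
#' @param seed Seed for mini-batch shuffling (default: the spec seed).
#' @return The model with fitted parameters, `trained = TRUE`, and a
#'   `history` data frame (`epoch`, `train_loss`, `val_loss`).
#' @export
train_predictor <- function(model, data,
                            epochs = NULL, learning_rate = NULL,
                            batch_size = NULL, patience = NULL,
                            seed = NULL) {
  stopifnot(inherits(model, "fitness_model"))
  if (!all(c("sequence", "score", "split") %in% names(data))) {
    stop("data needs columns sequence, score, split")
  }
  if (!any(data$split == "train") || !any(data$split == "val")) {
    stop("data must contain nonempty train and val splits")
  }
  if (any(!is.finite(data$score))) stop("non-finite fitness targets")
  spec <- model$spec
  epochs <- if (is.null(epochs)) spec$epochs else as.integer(epochs)
  learning_rate <- if (is.null(learning_rate)) spec$learning_rate else learning_rate
  batch_size <- if (is.null(batch_size)) spec$batch_size else as.integer(batch_size)
  patience <- if (is.null(patience)) spec$patience else as.integer(patience)
  seed <- if (is.null(seed)) spec$seed else seed

  Xtr <- encode_sequences(data$sequence[data$split == "train"], L = spec$L)
  ytr <- data$score[data$split == "train"]
  Xva <- encode_sequences(data$sequence[data$split == "val"], L = spec$L)
  yva <- data$score[data$split == "val"]
  n <- nrow(Xtr)

  mse <- function(pred, y) mean((pred - y)^2)
  loss_on <- function(X, y) mse(model_forward(model, X)$pred, y)

  history <- data.frame(epoch = 0L,
                        train_loss = loss_on(Xtr, ytr),
                        val_loss = loss_on(Xva, yva))
  best <- list(params = model$params, val = history$val_loss[1], epoch = 0L)
  state <- adam_init(model$params)
  wait <- 0L

  with_seed(seed, {
    for (epoch in seq_len(epochs)) {
      idx <- sample.int(n)
      starts <- seq(1L, n, by = batch_size)
      for (s in starts) {
        b <- idx[s:min(s + batch_size - 1L, n)]
        fw <- model_forward(model, Xtr[b, , drop = FALSE], want_cache = TRUE)
        dpred <- 2 * (fw$pred - ytr[b]) / length(b)
        grads <- model_backward(model, fw$cache, dpred)
        upd <- adam_step(model$params, grads, state, lr = learning_rate)
        model$params <- upd$params
        state <- upd$state
      }
      tr_loss <- loss_on(Xtr, ytr)
      va_loss <- loss_on(Xva, yva)
      history <- rbind(history, data.frame(epoch = epoch, train_loss = tr_loss,
                                           val_loss = va_loss))
      if (va_loss < best$val) {
        best <- list(params = model$params, val = va_loss, epoch = epoch)
        wait <- 0L
      } else {
        wait <- wait + 1L
        if (wait >= patience) break
      }
    }
  })
  model$params <- best$params
  model$history <- history
  model$best_epoch <- best$epoch
  model$trained <- TRUE
  model
}

#' Predict fitness for sequences
#'
#' Deterministic, batch-order-invariant prediction. Accepts a character
#' vector of sequences (length must match the model) or a pre-encoded
#' one-hot matrix.
#'
#' @param object A `fitness_model`.
#' @param newdata Character vector of sequences, or an n x (L*20) one-hot
#'   matrix from the package's encoder.
#' @param ... Unused.
#' @return Numeric vector of predicted fitness values.
#' @export
predict.fitness_model <- function(object, newdata, ...) {
  X <- if (is.character(newdata)) {
    encode_sequences(newdata, L = object$spec$L)
  } else {
    stopifnot(is.matrix(newdata), ncol(newdata) == object$spec$L * 20L)
    newdata
  }
  model_forward(object, X)$pred
}
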