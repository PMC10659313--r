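#' Specify a sequence-fitness predictor
#'
#' Defines one of the four supervised architectures mapping a one-hot
#' encoded protein sequence to a scalar fitness:
#'
#' * `linear` — one weight per position/amino-acid plus a bias; treats every
#'   residue position independently and is exactly additive in mutations.
#' * `fcn` — fully connected network (two ReLU hidden layers by default);
#'   can capture nonlinear behavior and epistasis.
#' * `cnn` — 1-D sequence convolutions (two valid-convolution layers with
#'   shared kernels) followed by a dense head; parameter sharing across the
#'   sequence lets it learn position-independent patterns.
#' * `gcn` — graph convolutions over a residue contact graph (two layers)
#'   followed by a dense head; propagates information between residues that
#'   are close in the protein structure, and therefore requires an
#'   adjacency matrix (see [contact_graph()]).
#'
#' The seed fully determines parameter initialization: two builds from the
#' same spec are parameter-identical.
#'
#' @param architecture One of `"linear"`, `"fcn"`, `"cnn"`, `"gcn"`.
#' @param L Sequence length the model accepts.
#' @param hidden Hidden-layer widths for `fcn` (default `c(100, 100)`).
#' @param kernel_size Convolution kernel width for `cnn` (default 5).
#' @param filters Convolution filters per layer for `cnn` (default 32).
#' @param channels Graph-convolution channels for `gcn` (default 32).
#' @param adjacency L x L symmetric 0/1 adjacency matrix (required for
#'   `gcn`); a [contact_graph()] object is accepted.
#' @param seed Initialization seed.
#' @param learning_rate,epochs,batch_size,patience Default training
#'   hyperparameters consumed by [train_predictor()].
#' @return Object of class `predictor_spec`.
#' @export
predictor_spec <- function(architecture = c("linear", "fcn", "cnn", "gcn"),
                           L,
                           hidden = c(100, 100),
                           kernel_size = 5,
                           filters = 32,
                           channels = 32,
                           adjacency = NULL,
                           seed = 0,
                           learning_rate = 1e-3,
                           epochs = 100,
                           batch_size = 64,
                           patience = 10) {
  architecture <- match.arg(architecture)
  L <- as.integer(L)
  stopifnot(L >= 1L)
  if (architecture == "gcn") {
    if (is.null(adjacency)) stop("gcn spec requires an adjacency matrix")
    if (inherits(adjacency, "contact_graph")) adjacency <- unclass(adjacency)
    adjacency <- as.matrix(adjacency)
    if (nrow(adjacency) != L || ncol(adjacency) != L) {
      stop("adjacency dimension (", nrow(adjacency),
           ") does not match L (", L, ")")
    }
    if (!isTRUE(all.equal(adjacency, t(adjacency)))) {
      stop("adjacency must be symmetric")
    }
  }
  if (architecture == "cnn" && L < 2L * kernel_size - 1L) {
    stop("sequence too short for two valid convolutions with kernel ",
         kernel_size)
  }
  structure(list(architecture = architecture, L = L, hidden = hidden,
                 kernel_size = as.integer(kernel_size),
                 filters = as.integer(filters),
                 channels = as.integer(channels),
                 adjacency = adjacency, seed = seed,
                 learning_rate = learning_rate, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 patience = as.integer(patience)),
            class = "predictor_spec")
}

#' Build an (untrained) predictor from a spec
#'
#' @param spec A [predictor_spec()].
#' @return Object of class `fitness_model` with initialized parameters;
#'   train it with [train_predictor()] or use as-is.
#' @export
build_model <- function(spec) {
  stopifnot(inherits(spec, "predictor_spec"))
  params <- with_seed(spec$seed, init_params(spec))
  model <- structure(list(spec = spec, params = params,
                          history = NULL, trained = FALSE,
                          tag = spec$architecture),
                     class = c(paste0("fitness_", spec$architecture),
                               "fitness_model"))
  if (spec$architecture == "gcn") {
    model$ahat <- normalize_adjacency(spec$adjacency)
  }
  model
}

#' @export
print.fitness_model <- function(x, ...) {
  cat("<fitness_model:", x$spec$architecture, "> L=", x$spec$L,
      ", ", n_params(x), " parameters, ",
      if (x$trained) "trained" else "untrained", "\n", sep = "")
  invisible(x)
}

#' Number of trainable parameters of a model
#'
#' @param model A [build_model()] object.
#' @return Integer parameter count (a linear model over L positions has
#'   `L * 20 + 1`).
#' @export
n_params <- function(model) {
  sum(vapply(model$params, length, 1L))
}

# Glorot-uniform initialization, fan-based.
glorot <- function(nin, nout) {
  lim <- sqrt(6 / (nin + nout))
  matrix(runif(nin * nout, -lim, lim), nrow = nin, ncol = nout)
}

init_params <- function(spec) {
  D <- spec$L * 20L
  switch(spec$architecture,
    linear = list(W = glorot(D, 1L), b = 0),
    fcn = {
      h <- spec$hidden
      list(W1 = glorot(D, h[1]), b1 = rep(0, h[1]),
           W2 = glorot(h[1], h[2]), b2 = rep(0, h[2]),
           W3 = glorot(h[2], 1L), b3 = 0)
    },
    cnn = {
      k <- spec$kernel_size; f <- spec$filters
      L2 <- spec$L - 2L * (k - 1L)
      list(K1 = glorot(k * 20L, f), b1 = rep(0, f),
           K2 = glorot(k * f, f), b2 = rep(0, f),
           W = glorot(L2 * f, 1L), b = 0)
    },
    gcn = {
      c_ <- spec$channels
      list(W1 = glorot(20L, c_), b1 = rep(0, c_),
           W2 = glorot(c_, c_), b2 = rep(0, c_),
           W = glorot(spec$L * c_, 1L), b = 0)
    })
}

# Symmetric renormalized adjacency with self loops (D^-1/2 (A+I) D^-1/2).
normalize_adjacency <- function(A) {
  A <- A + diag(nrow(A))
  d <- 1 / sqrt(rowSums(A))
  A * outer(d, d)
}
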