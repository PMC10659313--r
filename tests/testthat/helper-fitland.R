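# Shared fixtures: everything is generated in code at test time.

random_protein <- function(L, seed) {
  set.seed(seed)
  paste(sample(AA_ALPHABET, L, replace = TRUE), collapse = "")
}

# Small landscape + local dataset + splits in one call.
quick_dataset <- function(wt, epistasis_density = 0, double_fraction = 0.3,
                          noise_sd = 0, land_seed = 3, data_seed = 1,
                          split_seed = 2, ...) {
  land <- generate_landscape(wt, epistasis_density = epistasis_density,
                             seed = land_seed, ...)
  d <- sample_local_dataset(land, double_fraction = double_fraction,
                            noise_sd = noise_sd, seed = data_seed)
  list(landscape = land, data = assign_splits(d, seed = split_seed))
}

# Train a small model quickly on a prepared dataset.
quick_model <- function(arch, data, L, seed = 1, epochs = 60,
                        learning_rate = 0.03, hidden = c(32, 32),
                        filters = 8, channels = 8, adjacency = NULL,
                        batch_size = 256, patience = 15) {
  spec <- predictor_spec(arch, L = L, seed = seed,
                         learning_rate = learning_rate, epochs = epochs,
                         batch_size = batch_size, patience = patience,
                         hidden = hidden, filters = filters,
                         channels = channels, adjacency = adjacency)
  train_predictor(build_model(spec), data)
}

# A linear predictor with hand-set position/amino-acid weights (no training),
# handy as an exactly additive oracle. weights: L x 20 matrix.
manual_linear <- function(weights, bias = 0) {
  L <- nrow(weights)
  m <- build_model(predictor_spec("linear", L = L, seed = 0))
  m$params$W <- matrix(as.vector(t(weights)), ncol = 1)  # position-major
  m$params$b <- bias
  m$trained <- TRUE
  m
}

# A model that predicts a constant regardless of input.
constant_model <- function(L, value) {
  m <- build_model(predictor_spec("linear", L = L, seed = 0))
  m$params$W[] <- 0
  m$params$b <- value
  m
}
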