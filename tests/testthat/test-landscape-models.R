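# Small shared fixtures: one additive and one strongly epistatic landscape
# with matched local training data (L = 10 keeps training fast).
wt10 <- random_protein(10, seed = 55)
fix_add <- quick_dataset(wt10, epistasis_density = 0, double_fraction = 0.3)
fix_epi <- quick_dataset(wt10, epistasis_density = 0.25, epistasis_sd = 2,
                         double_fraction = 0.3, land_seed = 13)

# Pairwise epistatic terms in purely local double-mutant data are unique to
# their variant, so nothing can generalize them; learning epistasis requires
# terms that recur across variants. A combinatorial library at 4 sites makes
# every site-pair interaction reappear in hundreds of variants.
wt12c <- random_protein(12, seed = 88)
land_comb <- generate_landscape(wt12c, epistasis_density = 0.3,
                                epistasis_sd = 2, seed = 14)
fix_comb <- assign_splits(
  combinatorial_dataset(land_comb, sites = c(0, 3, 7, 11),
                        coverage_fraction = 0.04, noise_sd = 0.05, seed = 1),
  seed = 2)

test_that("model builds are seed-deterministic with the right capacity", {
  spec56 <- predictor_spec("linear", L = 56, seed = 1)
  expect_identical(n_params(build_model(spec56)), 56L * 20L + 1L)

  seqs <- vapply(1:5, function(i) random_protein(10, seed = 900 + i), "")
  for (arch in c("linear", "fcn", "cnn", "gcn")) {
    adj <- if (arch == "gcn") chain_contact_graph(10) else NULL
    spec <- predictor_spec(arch, L = 10, seed = 42, adjacency = adj,
                           hidden = c(16, 16), filters = 4, channels = 4)
    m1 <- build_model(spec)
    m2 <- build_model(spec)
    expect_gt(n_params(m1), 0L)
    expect_identical(m1$params, m2$params)
    expect_identical(predict(m1, seqs), predict(m2, seqs))
  }
  expect_error(predictor_spec("gcn", L = 10), "adjacency")
  expect_error(predictor_spec("gcn", L = 10,
                              adjacency = chain_contact_graph(8)),
               "does not match L")
  expect_error(predictor_spec("rnn", L = 10))
})

test_that("CNN convolutions are translation-equivariant", {
  spec <- predictor_spec("cnn", L = 12, seed = 3, filters = 6,
                         kernel_size = 3)
  m <- build_model(spec)
  # the same motif at two offsets in an otherwise constant background
  s1 <- paste0("WYF", strrep("A", 9))
  s2 <- paste0(strrep("A", 4), "WYF", strrep("A", 5))
  a1 <- fitland:::conv_activations(m, s1)  # 1 x L1 x filters
  a2 <- fitland:::conv_activations(m, s2)
  # activations fully inside the motif shift by exactly 4 positions
  expect_equal(a1[1, 1, ], a2[1, 5, ])
})

test_that("training fits the data and records an honest history", {
  # degenerate fit: all-constant targets are predicted to tolerance
  d_const <- fix_add$data
  d_const$score <- 2.5
  m <- quick_model("linear", d_const, L = 10, epochs = 120)
  expect_lt(max(abs(predict(m, d_const$sequence[1:20]) - 2.5)), 1e-3)

  # optimization sanity: best-epoch training loss <= initial loss
  m2 <- quick_model("fcn", fix_add$data, L = 10, epochs = 30)
  h <- m2$history
  expect_lte(h$train_loss[h$epoch == m2$best_epoch], h$train_loss[1])
  expect_identical(h$epoch[1], 0L)
  expect_error(train_predictor(build_model(predictor_spec("linear", L = 10)),
                               transform(fix_add$data, split = "train")),
               "val")
})

test_that("a linear model recovers additive effects from noiseless data", {
  m <- quick_model("linear", fix_add$data, L = 10, epochs = 250,
                   learning_rate = 0.05, patience = 60)
  W <- t(matrix(m$params$W, nrow = 20))       # L x 20, position-major
  wt_idx <- fitland:::seq_to_int(wt10)
  centered <- W - W[cbind(1:10, wt_idx)]      # effects relative to wild type
  r <- cor(as.vector(centered), as.vector(fix_add$landscape$additive))
  expect_gt(r, 0.99)
})

test_that("linear model predictions are exactly additive", {
  set.seed(61)
  weights <- matrix(rnorm(200), 10, 20)
  m <- manual_linear(weights, bias = 0.3)
  wt_chars <- strsplit(wt10, "")[[1]]
  for (i in 1:10) {
    p <- sample(0:9, 2)
    a <- vapply(p, function(q) sample(setdiff(AA_ALPHABET,
                                              wt_chars[q + 1]), 1), "")
    s1 <- apply_substitutions(wt10, p[1], a[1])
    s2 <- apply_substitutions(wt10, p[2], a[2])
    dd <- apply_substitutions(wt10, p, a)
    f <- predict(m, c(wt10, s1, s2, dd))
    expect_equal(f[4] - f[1], (f[2] - f[1]) + (f[3] - f[1]),
                 tolerance = 1e-6)
  }
})

test_that("prediction is deterministic and batch-order invariant", {
  m <- quick_model("cnn", fix_add$data, L = 10, epochs = 10)
  seqs <- fix_add$data$sequence[1:30]
  p1 <- predict(m, seqs)
  expect_identical(predict(m, seqs), p1)
  expect_equal(vapply(seqs, function(s) predict(m, s), 0,
                      USE.NAMES = FALSE), p1)
  perm <- sample(30)
  expect_equal(predict(m, seqs[perm]), p1[perm])
  expect_error(predict(m, "ACDEF"), "length")
})

test_that("nonlinear models beat the linear model on epistatic data", {
  # median over 5 seeds of validation loss at matched data
  val_loss <- function(m) min(m$history$val_loss)
  lin <- fcn <- cnn <- numeric(5)
  for (s in 1:5) {
    lin[s] <- val_loss(quick_model("linear", fix_comb, L = 12, seed = s,
                                   epochs = 80, learning_rate = 0.05))
    fcn[s] <- val_loss(quick_model("fcn", fix_comb, L = 12, seed = s,
                                   epochs = 80, learning_rate = 0.02))
    cnn[s] <- val_loss(quick_model("cnn", fix_comb, L = 12, seed = s,
                                   epochs = 80, learning_rate = 0.02))
  }
  expect_lt(median(fcn), median(lin))
  expect_lt(median(cnn), median(lin))
})

test_that("ensemble aggregation follows its order statistics", {
  # 100 constant members predicting 1..100
  members <- lapply(1:100, function(i) constant_model(10, i))
  ensm <- fitness_ensemble(members, "median")
  ensc <- fitness_ensemble(members, "percentile", p = 5)
  x <- random_protein(10, seed = 71)
  expect_equal(predict(ensm, x), 50.5)
  p5 <- predict(ensc, x)
  expect_gte(p5, 5)
  expect_lte(p5, 6)
  # all members identical -> ensemble equals the single member
  same <- fitness_ensemble(rep(list(constant_model(10, 3.2)), 7), "median")
  expect_equal(predict(same, x), 3.2)
  samec <- fitness_ensemble(rep(list(constant_model(10, 3.2)), 7),
                            "percentile")
  expect_equal(predict(samec, x), 3.2)
  expect_error(fitness_ensemble(list()), "at least one")
})

test_that("the conservative ensemble never exceeds the median ensemble", {
  members <- lapply(1:9, function(s) quick_model("fcn", fix_epi$data, L = 10,
                                                 seed = s, epochs = 15))
  ensm <- fitness_ensemble(members, "median")
  ensc <- fitness_ensemble(members, "percentile", p = 5)
  set.seed(81)
  seqs <- vapply(1:40, function(i) random_protein(10, seed = 1000 + i), "")
  expect_true(all(predict(ensc, seqs) <= predict(ensm, seqs) + 1e-12))
})

test_that("models trained from different seeds diverge away from the data", {
  m1 <- quick_model("cnn", fix_epi$data, L = 10, seed = 1, epochs = 40)
  m2 <- quick_model("cnn", fix_epi$data, L = 10, seed = 2, epochs = 40)
  near_sd <- far_sd <- numeric(6)
  for (t in 1:6) {
    traj <- mutational_trajectory(wt10, max_mutations = 9, seed = t)
    P <- member_predictions(list(m1, m2), traj)
    spread <- apply(P, 2, function(x) abs(diff(x)))
    near_sd[t] <- mean(spread[2:3])    # 1-2 mutations: training regime
    far_sd[t] <- mean(spread[9:10])    # 8-9 mutations: extrapolation
  }
  expect_gt(median(far_sd), median(near_sd))
})

test_that("contact graphs reflect the distance threshold", {
  # collinear chain spaced 3.8 A: only nearest neighbours within 4 A
  coords <- cbind(3.8 * (0:9), 0, 0)
  A <- contact_graph(coords, threshold = 4)
  band <- outer(1:10, 1:10, function(i, j) as.numeric(abs(i - j) == 1))
  expect_equal(unclass(A), band, ignore_attr = TRUE)
  expect_true(all(contact_graph(coords, threshold = 0) == 0))
  set.seed(91)
  rnd <- matrix(rnorm(30), 10, 3)
  Ar <- contact_graph(rnd, threshold = 1.5)
  expect_equal(unclass(Ar), t(unclass(Ar)), ignore_attr = TRUE)
  expect_true(all(diag(Ar) == 0))
  expect_error(contact_graph(rbind(rnd, NA)), "coordinates")
})

test_that("predictor checkpoints round-trip through JSON", {
  m <- quick_model("cnn", fix_add$data, L = 10, epochs = 8)
  path <- tempfile(fileext = ".json")
  save_predictor(m, path)
  m2 <- load_predictor(path)
  seqs <- fix_add$data$sequence[1:15]
  expect_equal(predict(m2, seqs), predict(m, seqs), tolerance = 1e-12)
  expect_true(m2$trained)
  unlink(path)
})
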