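# Forward/backward passes for the four architectures. All operate on the
# shared position-major one-hot layout produced by encode_sequences():
# X is n x (L*20), column (p-1)*20 + a. "Position-major row blocks" below
# means an (n*L) x C matrix whose row (p-1)*n + i holds sample i, position p.

relu <- function(x) {
  x[x < 0] <- 0
  x
}

add_bias <- function(Z, b) Z + rep(b, each = nrow(Z))

# --- reshape helpers -------------------------------------------------------

# n x (L*C) position-major columns  ->  (n*L) x C position-major row blocks
split_positions <- function(X, n, L, C) {
  R <- matrix(0, n * L, C)
  for (p in seq_len(L)) {
    R[(p - 1L) * n + seq_len(n), ] <- X[, ((p - 1L) * C + 1L):(p * C)]
  }
  R
}

# inverse of split_positions
join_positions <- function(H, n, L, C) {
  Z <- matrix(0, n, L * C)
  for (p in seq_len(L)) {
    Z[, ((p - 1L) * C + 1L):(p * C)] <- H[(p - 1L) * n + seq_len(n), ]
  }
  Z
}

# sliding windows over the raw one-hot input: (n*L1) x (k*20)
im2col_input <- function(X, n, L, k) {
  L1 <- L - k + 1L
  M <- matrix(0, n * L1, k * 20L)
  for (p in seq_len(L1)) {
    M[(p - 1L) * n + seq_len(n), ] <- X[, ((p - 1L) * 20L + 1L):((p + k - 1L) * 20L)]
  }
  M
}

# sliding windows over feature maps in position-major row blocks
im2col_feat <- function(H, n, L1, k, f) {
  L2 <- L1 - k + 1L
  M <- matrix(0, n * L2, k * f)
  for (q in seq_len(L2)) {
    rows <- (q - 1L) * n + seq_len(n)
    for (j in seq_len(k)) {
      M[rows, ((j - 1L) * f + 1L):(j * f)] <- H[(q + j - 2L) * n + seq_len(n), ]
    }
  }
  M
}

# scatter-add gradient of im2col_feat back onto the feature map
col2im_feat <- function(dM, n, L1, k, f) {
  L2 <- L1 - k + 1L
  dH <- matrix(0, n * L1, f)
  for (q in seq_len(L2)) {
    rows <- (q - 1L) * n + seq_len(n)
    for (j in seq_len(k)) {
      tgt <- (q + j - 2L) * n + seq_len(n)
      dH[tgt, ] <- dH[tgt, ] + dM[rows, ((j - 1L) * f + 1L):(j * f)]
    }
  }
  dH
}

# apply the normalized adjacency across positions of position-major blocks
graph_prop <- function(H, ahat, n, L, C) {
  a <- array(H, c(n, L, C))
  m <- matrix(aperm(a, c(2L, 1L, 3L)), L, n * C)
  pm <- ahat %*% m
  matrix(aperm(array(pm, c(L, n, C)), c(2L, 1L, 3L)), n * L, C)
}

# --- architecture forward/backward ----------------------------------------

model_forward <- function(model, X, want_cache = FALSE) {
  p <- model$params
  n <- nrow(X)
  spec <- model$spec
  switch(spec$architecture,
    linear = {
      pred <- drop(X %*% p$W) + p$b
      list(pred = pred, cache = if (want_cache) list(X = X))
    },
    fcn = {
      Z1 <- add_bias(X %*% p$W1, p$b1); A1 <- relu(Z1)
      Z2 <- add_bias(A1 %*% p$W2, p$b2); A2 <- relu(Z2)
      pred <- drop(A2 %*% p$W3) + p$b3
      list(pred = pred,
           cache = if (want_cache) list(X = X, Z1 = Z1, A1 = A1,
                                        Z2 = Z2, A2 = A2))
    },
    cnn = {
      k <- spec$kernel_size; f <- spec$filters
      L <- spec$L; L1 <- L - k + 1L; L2 <- L1 - k + 1L
      M1 <- im2col_input(X, n, L, k)
      Z1 <- add_bias(M1 %*% p$K1, p$b1); A1 <- relu(Z1)
      M2 <- im2col_feat(A1, n, L1, k, f)
      Z2 <- add_bias(M2 %*% p$K2, p$b2); A2 <- relu(Z2)
      Zf <- join_positions(A2, n, L2, f)
      pred <- drop(Zf %*% p$W) + p$b
      list(pred = pred,
           cache = if (want_cache) list(M1 = M1, Z1 = Z1, M2 = M2,
                                        Z2 = Z2, Zf = Zf))
    },
    gcn = {
      C <- spec$channels
      L <- spec$L
      XL <- split_positions(X, n, L, 20L)
      P0 <- graph_prop(XL, model$ahat, n, L, 20L)
      Z1 <- add_bias(P0 %*% p$W1, p$b1); A1 <- relu(Z1)
      P1 <- graph_prop(A1, model$ahat, n, L, C)
      Z2 <- add_bias(P1 %*% p$W2, p$b2); A2 <- relu(Z2)
      Zf <- join_positions(A2, n, L, C)
      pred <- drop(Zf %*% p$W) + p$b
      list(pred = pred,
           cache = if (want_cache) list(P0 = P0, Z1 = Z1, P1 = P1,
                                        Z2 = Z2, Zf = Zf))
    })
}

# dpred is dLoss/dpred as an n-vector; returns gradients shaped like params.
model_backward <- function(model, cache, dpred) {
  p <- model$params
  spec <- model$spec
  n <- length(dpred)
  dp <- matrix(dpred, ncol = 1L)
  switch(spec$architecture,
    linear = list(W = crossprod(cache$X, dp), b = sum(dpred)),
    fcn = {
      dA2 <- dp %*% t(p$W3)
      dZ2 <- dA2 * (cache$Z2 > 0)
      dA1 <- dZ2 %*% t(p$W2)
      dZ1 <- dA1 * (cache$Z1 > 0)
      list(W1 = crossprod(cache$X, dZ1), b1 = colSums(dZ1),
           W2 = crossprod(cache$A1, dZ2), b2 = colSums(dZ2),
           W3 = crossprod(cache$A2, dp), b3 = sum(dpred))
    },
    cnn = {
      k <- spec$kernel_size; f <- spec$filters
      L <- spec$L; L1 <- L - k + 1L; L2 <- L1 - k + 1L
      dZf <- dp %*% t(p$W)
      dA2 <- split_positions(dZf, n, L2, f)
      dZ2 <- dA2 * (cache$Z2 > 0)
      dM2 <- dZ2 %*% t(p$K2)
      dA1 <- col2im_feat(dM2, n, L1, k, f)
      dZ1 <- dA1 * (cache$Z1 > 0)
      list(K1 = crossprod(cache$M1, dZ1), b1 = colSums(dZ1),
           K2 = crossprod(cache$M2, dZ2), b2 = colSums(dZ2),
           W = crossprod(cache$Zf, dp), b = sum(dpred))
    },
    gcn = {
      C <- spec$channels
      L <- spec$L
      dZf <- dp %*% t(p$W)
      dA2 <- split_positions(dZf, n, L, C)
      dZ2 <- dA2 * (cache$Z2 > 0)
      dP1 <- dZ2 %*% t(p$W2)
      dA1 <- graph_prop(dP1, model$ahat, n, L, C)  # ahat is symmetric
      dZ1 <- dA1 * (cache$Z1 > 0)
      list(W1 = crossprod(cache$P0, dZ1), b1 = colSums(dZ1),
           W2 = crossprod(cache$P1, dZ2), b2 = colSums(dZ2),
           W = crossprod(cache$Zf, dp), b = sum(dpred))
    })
}

# First-convolution-layer activations (pre-pooling feature maps) for a CNN,
# as an n x L1 x filters array. Used to probe translation equivariance.
conv_activations <- function(model, seqs) {
  stopifnot(model$spec$architecture == "cnn")
  X <- encode_sequences(seqs, L = model$spec$L)
  n <- nrow(X)
  k <- model$spec$kernel_size
  L1 <- model$spec$L - k + 1L
  M1 <- im2col_input(X, n, model$spec$L, k)
  A1 <- relu(add_bias(M1 %*% model$params$K1, model$params$b1))
  array(A1, c(n, L1, model$spec$filters))
}

# --- Adam optimizer --------------------------------------------------------

adam_init <- function(params) {
  list(m = lapply(params, function(x) x * 0),
       v = lapply(params, function(x) x * 0),
       t = 0L)
}

adam_step <- function(params, grads, state, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  corr1 <- 1 - beta1^state$t
  corr2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    mhat <- state$m[[nm]] / corr1
    vhat <- state$v[[nm]] / corr2
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}
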