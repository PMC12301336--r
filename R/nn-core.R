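# Forward/backward primitives for the attention pooling block and the MLPs.
# Everything is plain dense linear algebra; each *_fwd returns the output
# plus the cache its *_bwd needs. Gradient correctness is pinned by the
# numeric-vs-analytic gradient-check test.

LN_EPS <- 1e-5

layernorm_fwd <- function(X, g, b) {
  d <- ncol(X)
  mu <- rowMeans(X)
  xc <- X - mu
  v <- rowSums(xc^2) / d
  inv <- 1 / sqrt(v + LN_EPS)
  xhat <- xc * inv
  out <- bias_add(col_scale(xhat, g), b)
  list(out = out, cache = list(xhat = xhat, inv = inv, g = g, d = d))
}

layernorm_bwd <- function(dout, cache) {
  xhat <- cache$xhat; inv <- cache$inv; d <- cache$d
  dxhat <- col_scale(dout, cache$g)
  dg <- colSums(dout * xhat)
  db <- colSums(dout)
  rs1 <- rowSums(dxhat)
  rs2 <- rowSums(dxhat * xhat)
  dX <- (dxhat - rs1 / d - xhat * rs2 / d) * inv
  list(dX = dX, dg = dg, db = db)
}

dropout_mask <- function(nr, nc, rate) {
  if (rate <= 0) return(NULL)
  matrix((runif(nr * nc) >= rate) / (1 - rate), nr, nc)
}

apply_mask <- function(X, mask) if (is.null(mask)) X else X * mask

# --- multi-head scaled dot-product attention ------------------------------

init_attention_params <- function(model_dim = 128, heads = 2, d_k = 32,
                                  seed = NULL) {
  make <- function() {
    list(
      heads = lapply(seq_len(heads), function(i) list(
        Wq = glorot(model_dim, d_k),
        Wk = glorot(model_dim, d_k),
        Wv = glorot(model_dim, d_k)
      )),
      Wo = glorot(heads * d_k, model_dim)
    )
  }
  if (is.null(seed)) make() else withr_seed(seed, make())
}

# All per-head Q/K/V projections are fused into one matmul against the
# column-bound weight matrix; heads are then views into the projection.
mha_fwd <- function(X, params) {
  T_ <- nrow(X)
  hlist <- params$heads
  d_k <- ncol(hlist[[1]]$Wq)
  scale <- 1 / sqrt(d_k)
  Wall <- do.call(cbind, lapply(hlist, function(hp) cbind(hp$Wq, hp$Wk, hp$Wv)))
  PRJ <- X %*% Wall # T x (3 * heads * d_k)
  check_finite(PRJ, "attention projections")
  caches <- vector("list", length(hlist))
  scores <- vector("list", length(hlist))
  M <- matrix(0, T_, length(hlist) * d_k)
  for (i in seq_along(hlist)) {
    base <- (i - 1) * 3 * d_k
    Q <- PRJ[, (base + 1):(base + d_k), drop = FALSE]
    K <- PRJ[, (base + d_k + 1):(base + 2 * d_k), drop = FALSE]
    V <- PRJ[, (base + 2 * d_k + 1):(base + 3 * d_k), drop = FALSE]
    S <- tcrossprod(Q, K) * scale
    check_finite(S, "attention logits")
    P <- softmax_rows(S)
    H <- P %*% V
    M[, ((i - 1) * d_k + 1):(i * d_k)] <- H
    caches[[i]] <- list(Q = Q, K = K, V = V, P = P)
    scores[[i]] <- P
  }
  out <- M %*% params$Wo
  list(
    out = out, scores = scores,
    cache = list(X = X, M = M, caches = caches, d_k = d_k, scale = scale,
      Wall = Wall)
  )
}

mha_bwd <- function(dout, cache, params) {
  X <- cache$X
  d_k <- cache$d_k
  scale <- cache$scale
  dM <- dout %*% t(params$Wo)
  dWo <- crossprod(cache$M, dout)
  dPRJ <- matrix(0, nrow(X), ncol(cache$Wall))
  gheads <- vector("list", length(params$heads))
  for (i in seq_along(params$heads)) {
    hc <- cache$caches[[i]]
    dH <- dM[, ((i - 1) * d_k + 1):(i * d_k), drop = FALSE]
    dP <- tcrossprod(dH, hc$V)
    dV <- crossprod(hc$P, dH)
    dS <- hc$P * (dP - rowSums(dP * hc$P))
    dQ <- (dS %*% hc$K) * scale
    dK <- (crossprod(dS, hc$Q)) * scale
    base <- (i - 1) * 3 * d_k
    dPRJ[, (base + 1):(base + 3 * d_k)] <- cbind(dQ, dK, dV)
    gheads[[i]] <- i # placeholder, filled from the fused gradient below
  }
  gWall <- crossprod(X, dPRJ)
  for (i in seq_along(params$heads)) {
    base <- (i - 1) * 3 * d_k
    gheads[[i]] <- list(
      Wq = gWall[, (base + 1):(base + d_k), drop = FALSE],
      Wk = gWall[, (base + d_k + 1):(base + 2 * d_k), drop = FALSE],
      Wv = gWall[, (base + 2 * d_k + 1):(base + 3 * d_k), drop = FALSE]
    )
  }
  list(dX = tcrossprod(dPRJ, cache$Wall), grads = list(heads = gheads, Wo = dWo))
}

# --- transformer encoder layer (post-norm, ReLU feed-forward) -------------

init_encoder_params <- function(model_dim = 128, heads = 2, d_k = 32,
                                ffn_dim = 64, seed = NULL) {
  make <- function() {
    list(
      attn = init_attention_params(model_dim, heads, d_k),
      W1 = glorot(model_dim, ffn_dim), b1 = numeric(ffn_dim),
      W2 = glorot(ffn_dim, model_dim), b2 = numeric(model_dim),
      ln1 = list(g = rep(1, model_dim), b = numeric(model_dim)),
      ln2 = list(g = rep(1, model_dim), b = numeric(model_dim))
    )
  }
  if (is.null(seed)) make() else withr_seed(seed, make())
}

encoder_fwd <- function(X, params, dropout = 0, train_mode = FALSE) {
  encoder_fwd_cpp(X, params, dropout, train_mode)
}

encoder_bwd <- function(dout, cache, params) {
  encoder_bwd_cpp(dout, cache, params)
}

# --- elementwise accumulation over nested parameter/gradient lists --------

zero_like <- function(p) {
  if (is.list(p)) lapply(p, zero_like) else p * 0
}

acc_grads <- function(a, b) {
  if (is.null(a)) return(b)
  if (is.null(b)) return(a)
  if (is.list(a)) {
    for (k in seq_along(a)) a[[k]] <- acc_grads(a[[k]], b[[k]])
    a
  } else {
    a + b
  }
}

scale_grads <- function(a, s) {
  if (is.list(a)) lapply(a, scale_grads, s = s) else a * s
}
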