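# Shared fixtures and independent oracles, built once per test run.

# Small triplet table used by the preprocessing tests.
tiny_records <- function() {
  tibble::tibble(
    drug_a = c("A", "B", "A", "C"),
    drug_b = c("B", "A", "C", "A"),
    smiles_a = "C",
    smiles_b = "CC",
    cell_line = c("cl1", "cl1", "cl1", "cl2"),
    score = c(8, 12, 15, -4)
  )
}

# Memoized small synthetic study (fast: tiny graph, few triplets).
tiny_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- make_fixture_dataset(fixture_config(
        n_drugs = 8, n_cell_lines = 6, n_genes = 20, n_triplets = 150,
        noise = 0, seed = 42
      ))
    }
    cache
  }
})

# Small PPI embedding for the tiny fixture (memoized).
tiny_embedding <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      fx <- tiny_fixture()
      emb <- embed_network(fx$ppi,
        walk_config(dim = 16, walks_per_node = 3, walk_length = 20,
          epochs = 2, seed = 7),
        cache_dir = FALSE)
      cache <<- align_embedding(emb, setdiff(names(fx$expression), "cell_line"))
    }
    cache
  }
})

# Reduced model configuration compatible with the tiny fixture.
tiny_config <- function(...) {
  args <- utils::modifyList(list(
    gcn_dims = c(78, 32, 16), chem_dim = 64, cell_hidden = c(32, 24, 16),
    heads = 2, d_k = 4, ffn_dim = 8, n_layers = 2, pool_dim = 12,
    clf_hidden = c(16, 8, 4), epochs = 3, batch_size = 64, seed = 5
  ), list(...))
  do.call(model_config, args)
}

tiny_backend <- function() chem_backend(dim = 64)

# Memoized tiny trained model shared by prediction/interpretation tests.
tiny_model <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      fx <- tiny_fixture()
      cache <<- train_model(fx$triplets, fx$expression, tiny_embedding(),
        tiny_config(), backend = tiny_backend(), quiet = TRUE)
    }
    cache
  }
})

# --- independent oracles --------------------------------------------------

# Brute-force multi-head attention: explicit loops over tokens and heads.
oracle_multi_head_attention <- function(X, params) {
  T_ <- nrow(X)
  d_k <- ncol(params$heads[[1]]$Wq)
  heads_out <- list()
  for (h in seq_along(params$heads)) {
    hp <- params$heads[[h]]
    Q <- X %*% hp$Wq; K <- X %*% hp$Wk; V <- X %*% hp$Wv
    H <- matrix(0, T_, d_k)
    for (i in seq_len(T_)) {
      logits <- numeric(T_)
      for (j in seq_len(T_)) {
        logits[j] <- sum(Q[i, ] * K[j, ]) / sqrt(d_k)
      }
      w <- exp(logits - max(logits))
      w <- w / sum(w)
      for (d in seq_len(d_k)) {
        H[i, d] <- sum(w * V[, d])
      }
    }
    heads_out[[h]] <- H
  }
  do.call(cbind, heads_out) %*% params$Wo
}

# Pairwise AUROC oracle: mean over all (pos, neg) pairs with ties as 1/2.
oracle_auroc <- function(truth, probs) {
  pos <- probs[truth == 1]
  neg <- probs[truth == 0]
  s <- 0
  for (p in pos) {
    for (n in neg) {
      s <- s + (p > n) + 0.5 * (p == n)
    }
  }
  s / (length(pos) * length(neg))
}

# Enumerate node2vec second-order transition weights directly.
oracle_step_probs <- function(adj, prev, current, p, q) {
  cand <- which(adj[current, ] == 1)
  if (length(cand) == 0) return(NULL)
  w <- vapply(cand, function(x) {
    if (x == prev) 1 / p else if (adj[prev, x] == 1) 1 else 1 / q
  }, numeric(1))
  stats::setNames(w / sum(w), cand)
}
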