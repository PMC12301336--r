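# The 2D feature core: drug-atom and protein tokens pooled through
# transformer encoder layers with multi-head attention.

#' Assemble the attention token matrix for a drug pair
#'
#' Stacks, in order, drug-A atom embeddings, drug-B atom embeddings, and
#' protein node embeddings into one token matrix, recording which row plays
#' which role. Tokens are set-structured — there is no positional encoding —
#' which is what makes the pooled 2D feature permutation invariant.
#'
#' @param atom_emb_a,atom_emb_b atom-embedding matrices (V x 128) from
#'   [gcn_forward()].
#' @param ppi_table node-embedding matrix (genes x 128) with gene-symbol
#'   rownames, from [embed_network()].
#' @param elements_a,elements_b optional atom element symbols used as row
#'   labels in attention views.
#' @return A `drugsyn_tokens`: list with `X` (T x 128) and `roles`, a tibble
#'   with columns `role` (`atomA`/`atomB`/`gene`), `label`, `index`.
#' @export
assemble_tokens <- function(atom_emb_a, atom_emb_b, ppi_table,
                            elements_a = NULL, elements_b = NULL) {
  w <- c(ncol(atom_emb_a), ncol(atom_emb_b), ncol(ppi_table))
  assert_that(length(unique(w)) == 1, sprintf(
    "embedding widths differ: %s", paste(w, collapse = ", ")
  ))
  va <- nrow(atom_emb_a); vb <- nrow(atom_emb_b); ng <- nrow(ppi_table)
  lab_a <- if (is.null(elements_a)) paste0("A", seq_len(va)) else
    paste0(elements_a, ":", seq_len(va))
  lab_b <- if (is.null(elements_b)) paste0("B", seq_len(vb)) else
    paste0(elements_b, ":", seq_len(vb))
  genes <- rownames(ppi_table) %||% paste0("G", seq_len(ng))
  structure(
    list(
      X = rbind(unname(atom_emb_a), unname(atom_emb_b), unname(ppi_table)),
      roles = tibble(
        role = rep(c("atomA", "atomB", "gene"), c(va, vb, ng)),
        label = c(lab_a, lab_b, genes),
        index = c(seq_len(va), seq_len(vb), seq_len(ng))
      )
    ),
    class = "drugsyn_tokens"
  )
}

#' @export
print.drugsyn_tokens <- function(x, ...) {
  tab <- table(x$roles$role)
  cat(sprintf(
    "<drugsyn_tokens> %d tokens (%s), width %d\n",
    nrow(x$X),
    paste(sprintf("%s=%d", names(tab), tab), collapse = ", "),
    ncol(x$X)
  ))
  invisible(x)
}

token_matrix <- function(x) {
  if (inherits(x, "drugsyn_tokens")) x$X else as.matrix(x)
}

#' Multi-head scaled dot-product attention
#'
#' For each head \eqn{i}, projects the tokens into query, key, and value
#' matrices \eqn{Q_i = X W_i^Q}, \eqn{K_i = X W_i^K}, \eqn{V_i = X W_i^V},
#' computes \eqn{\mathrm{softmax}(Q_i K_i^\top / \sqrt{d_k}) V_i},
#' concatenates the heads, and projects once more with \eqn{W^O}.
#'
#' @param x a `drugsyn_tokens` or a plain token matrix.
#' @param params attention parameters from [init_attention_params()].
#' @return list with `output` (T x model_dim) and `records`, a list of
#'   `drugsyn_attention` records (one per head) whose score-matrix rows are
#'   non-negative and sum to 1.
#' @export
multi_head_attention <- function(x, params) {
  X <- token_matrix(x)
  fwd <- mha_fwd(X, params)
  roles <- if (inherits(x, "drugsyn_tokens")) x$roles else NULL
  records <- lapply(seq_along(fwd$scores), function(i) {
    new_attention_record(layer = 1L, head = i, scores = fwd$scores[[i]], roles = roles)
  })
  list(output = fwd$out, records = records)
}

new_attention_record <- function(layer, head, scores, roles) {
  structure(
    list(layer = layer, head = head, scores = scores, roles = roles),
    class = "drugsyn_attention"
  )
}

#' @export
print.drugsyn_attention <- function(x, ...) {
  cat(sprintf(
    "<drugsyn_attention> layer %d, head %d, %d x %d scores\n",
    x$layer, x$head, nrow(x$scores), ncol(x$scores)
  ))
  invisible(x)
}

#' One transformer encoder layer
#'
#' Post-norm residual encoder: `LayerNorm(X + MHA(X))` followed by
#' `LayerNorm(y + FFN(y))` where `FFN(y) = ReLU(y W1 + b1) W2 + b2`.
#' Evaluation mode (no dropout).
#'
#' @param x a `drugsyn_tokens` or token matrix.
#' @param params encoder parameters from [init_encoder_params()].
#' @return matrix of the same shape as the input tokens.
#' @export
transformer_encoder_layer <- function(x, params) {
  X <- token_matrix(x)
  encoder_fwd(X, params, dropout = 0, train_mode = FALSE)$out
}

#' Initialize a graph-trans pooling stack
#'
#' @param model_dim token width (default 128, matching the GCN and node2vec
#'   output widths).
#' @param heads attention heads per layer (default 2).
#' @param d_k per-head query/key width (default 32, so heads x d_k gives the
#'   64-wide hidden projection).
#' @param ffn_dim feed-forward inner width (default 64).
#' @param n_layers encoder layers (default 2).
#' @param pool_dim pooled output width (default 256).
#' @param dropout dropout rate in training mode (default 0.3).
#' @param seed integer seed.
#' @return list of class `drugsyn_graph_trans`.
#' @export
init_graph_trans <- function(model_dim = 128, heads = 2, d_k = 32,
                             ffn_dim = 64, n_layers = 2, pool_dim = 256,
                             dropout = 0.3, seed = 1) {
  withr_seed(seed, structure(
    list(
      layers = lapply(seq_len(n_layers), function(l) {
        init_encoder_params(model_dim, heads, d_k, ffn_dim)
      }),
      Wp = glorot(model_dim, pool_dim),
      bp = numeric(pool_dim),
      dropout = dropout
    ),
    class = "drugsyn_graph_trans"
  ))
}

#' Pool a token matrix into the 2D feature vector
#'
#' Runs the token matrix through the encoder stack, mean-pools over tokens,
#' and applies a fully connected ReLU layer, yielding the 256-d 2D feature.
#' Attention score records from every layer and head are returned alongside.
#'
#' @param tokens a `drugsyn_tokens`.
#' @param stack a `drugsyn_graph_trans` from [init_graph_trans()].
#' @return list with `feature` (numeric, length `pool_dim`) and `records`
#'   (list of `drugsyn_attention`, `n_layers * heads` entries).
#' @export
graph_trans_pool <- function(tokens, stack) {
  X <- token_matrix(tokens)
  roles <- if (inherits(tokens, "drugsyn_tokens")) tokens$roles else NULL
  records <- list()
  for (l in seq_along(stack$layers)) {
    fwd <- encoder_fwd(X, stack$layers[[l]], dropout = 0, train_mode = FALSE)
    X <- fwd$out
    for (i in seq_along(fwd$scores)) {
      records[[length(records) + 1]] <- new_attention_record(
        layer = l, head = i, scores = fwd$scores[[i]], roles = roles
      )
    }
  }
  m <- matrix(colMeans(X), nrow = 1)
  feature <- as.numeric(relu(m %*% stack$Wp + matrix(stack$bp, 1)))
  list(feature = feature, records = records)
}
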