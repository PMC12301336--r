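# 1D feature embedding: chemical-language drug vectors (pluggable backend)
# and the three-layer MLP that compresses landmark-gene expression.

#' Choose a chemical-language embedding backend
#'
#' The drug-vector model is an interface, not a dependency. The
#' `hashed_fallback` backend (default) computes a deterministic 768-d
#' vector offline by feature-hashing circular substructure identifiers
#' (Morgan-style, radius 2) into 768 signed buckets followed by L2
#' normalization. The `pretrained` tag is reserved for plugging in a
#' fine-tuned transformer chemistry model via `embed_fun`; selecting it
#' without supplying `embed_fun` is an error suggesting the fallback.
#'
#' @param backend `"hashed_fallback"` or `"pretrained"`.
#' @param dim output dimensionality (default 768).
#' @param radius circular-substructure radius for the fallback (default 2).
#' @param embed_fun optional function `(smiles) -> numeric(dim)` powering
#'   the pretrained backend.
#' @return list of class `drugsyn_chem_backend`.
#' @export
chem_backend <- function(backend = c("hashed_fallback", "pretrained"),
                         dim = 768, radius = 2, embed_fun = NULL) {
  backend <- match.arg(backend)
  if (backend == "pretrained" && is.null(embed_fun)) {
    abort(paste(
      "pretrained chemical-language backend is not bundled;",
      "supply embed_fun or use chem_backend('hashed_fallback')"
    ))
  }
  structure(
    list(backend = backend, dim = dim, radius = radius, embed_fun = embed_fun),
    class = "drugsyn_chem_backend"
  )
}

#' Embed a SMILES string as a 768-d drug vector
#'
#' @param smiles a single SMILES string.
#' @param backend a [chem_backend()]; default is the hashed fallback.
#' @return numeric vector of length `backend$dim`; under the fallback it has
#'   unit L2 norm (unless the molecule yields no identifiers, which cannot
#'   happen for a valid molecule).
#' @export
#' @examples
#' v <- embed_smiles("CCO")
#' sqrt(sum(v^2))
embed_smiles <- function(smiles, backend = chem_backend()) {
  if (backend$backend == "pretrained") {
    v <- backend$embed_fun(smiles)
    assert_that(length(v) == backend$dim, "pretrained backend returned wrong width")
    check_finite(v, "pretrained drug embedding")
    return(as.numeric(v))
  }
  graph <- smiles_to_graph(smiles)
  ids <- morgan_identifiers(graph, backend$radius)
  v <- numeric(backend$dim)
  for (id in ids) {
    bucket <- (id %% backend$dim) + 1
    sign <- if ((id %/% backend$dim) %% 2 == 0) 1 else -1
    v[bucket] <- v[bucket] + sign
  }
  nrm <- sqrt(sum(v^2))
  if (nrm > 0) v <- v / nrm
  v
}

# Circular substructure identifiers: iteratively hash each atom's invariant
# with its neighbours' invariants, collecting one identifier per (atom,
# radius) as in ECFP generation. Returns the multiset of identifiers.
morgan_identifiers <- function(graph, radius = 2) {
  V <- nrow(graph$A)
  nbrs <- lapply(seq_len(V), function(i) which(graph$A[i, ] == 1))
  # initial invariant from the discrete atom descriptors
  inv <- vapply(seq_len(V), function(i) {
    hash_ints(c(
      match(graph$elements[i], ATOM_SYMBOLS, nomatch = length(ATOM_SYMBOLS)),
      sum(graph$A[i, ]),
      as.integer(graph$aromatic[i]),
      which(graph$X[i, 45:55] == 1), # degree block
      which(graph$X[i, 56:66] == 1)  # attached-H block
    ))
  }, numeric(1))
  ids <- inv
  for (r in seq_len(radius)) {
    inv <- vapply(seq_len(V), function(i) {
      hash_ints(c(r, inv[i], sort(inv[nbrs[[i]]])))
    }, numeric(1))
    ids <- c(ids, inv)
  }
  ids
}

#' Initialize the cell-line encoder parameters
#'
#' Three dense layers compressing a landmark-gene expression vector;
#' default widths 978 -> 768 -> 512 -> 256 with ReLU after the first two
#' layers and dropout during training.
#'
#' @param n_genes input gene count (default 978).
#' @param hidden widths of the three layers (default `c(768, 512, 256)`).
#' @param dropout dropout rate used in training mode (default 0.3).
#' @param seed integer seed.
#' @return list of class `drugsyn_cell_encoder` with weight/bias chain.
#' @export
init_cell_encoder <- function(n_genes = 978, hidden = c(768, 512, 256),
                              dropout = 0.3, seed = 1) {
  assert_that(length(hidden) == 3, "cell-line encoder has three layers")
  dims <- c(n_genes, hidden)
  withr_seed(seed, structure(
    list(
      W = lapply(1:3, function(l) glorot(dims[l], dims[l + 1])),
      b = lapply(1:3, function(l) numeric(dims[l + 1])),
      dropout = dropout
    ),
    class = "drugsyn_cell_encoder"
  ))
}

#' Encode a cell line's expression vector
#'
#' @param expression numeric vector of per-gene expression (z-scored), its
#'   length matching the encoder's configured gene count.
#' @param params a `drugsyn_cell_encoder`.
#' @param train_mode logical; dropout is active only when `TRUE`.
#' @return numeric vector of length 256 (the final layer width).
#' @export
encode_cell_line <- function(expression, params, train_mode = FALSE) {
  assert_that(length(expression) == nrow(params$W[[1]]), sprintf(
    "expression length %d does not match encoder input width %d",
    length(expression), nrow(params$W[[1]])
  ))
  h <- matrix(expression, nrow = 1)
  for (l in 1:3) {
    h <- h %*% params$W[[l]] + matrix(params$b[[l]], 1)
    if (l < 3) h <- relu(h)
    if (train_mode && params$dropout > 0) {
      mask <- (runif(ncol(h)) >= params$dropout) / (1 - params$dropout)
      h <- h * rep(mask, each = nrow(h))
    }
  }
  check_finite(h, "cell-line encoding")
  as.numeric(h)
}

#' Fuse the 1D features of a triplet
#'
#' Concatenates, in order, the drug-A vector (768), the drug-B vector (768),
#' and the compressed cell-line vector (256) into the 1792-d 1D feature.
#'
#' @param vec_a,vec_b drug vectors of equal length.
#' @param cell_vec compressed cell-line vector.
#' @return numeric vector of length `2 * length(vec_a) + length(cell_vec)`.
#' @export
fuse_1d <- function(vec_a, vec_b, cell_vec) {
  assert_that(length(vec_a) == length(vec_b), "drug vectors must have equal length")
  c(vec_a, vec_b, cell_vec)
}

#' Per-gene z-score statistics from training cell lines
#'
#' @param expression expression tibble (or matrix with cell-line rownames).
#' @param cell_lines cell lines to compute the statistics over (default all).
#' @return list with `mean` and `sd` vectors (sd floored at 1e-8).
#' @export
expression_zscore_stats <- function(expression, cell_lines = NULL) {
  m <- expression_to_matrix(expression)
  if (!is.null(cell_lines)) m <- m[intersect(rownames(m), cell_lines), , drop = FALSE]
  mu <- colMeans(m)
  sdv <- apply(m, 2, sd)
  sdv[!is.finite(sdv) | sdv < 1e-8] <- 1
  list(mean = mu, sd = sdv)
}

apply_zscore <- function(m, stats) {
  sweep(sweep(m, 2, stats$mean, "-"), 2, stats$sd, "/")
}
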