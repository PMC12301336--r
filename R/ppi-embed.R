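# node2vec embedding of the landmark-gene PPI network: second-order biased
# random walks plus skip-gram with negative sampling (src/skipgram.cpp).

#' Read a protein-protein interaction edge list
#'
#' Two-column tab-separated text of gene symbols, one undirected edge per
#' row. Self-loops and duplicate edges (in either orientation) are removed.
#'
#' @param path path to the edge-list file.
#' @param nodes optional character vector of node symbols to align with
#'   (e.g. the expression matrix gene order); nodes absent from the edge
#'   list become isolated vertices.
#' @return A `drugsyn_ppi`: list with `nodes` (character) and `edges`
#'   (two-column character matrix).
#' @export
load_ppi_network <- function(path, nodes = NULL) {
  df <- readr::read_tsv(path, col_names = c("a", "b"), col_types = "cc",
    progress = FALSE)
  ppi_network(df$a, df$b, nodes = nodes)
}

#' Construct a PPI network from edge endpoint vectors
#'
#' @param from,to character vectors of gene symbols (equal length).
#' @param nodes optional full node list (see [load_ppi_network()]).
#' @return a `drugsyn_ppi` object.
#' @export
ppi_network <- function(from, to, nodes = NULL) {
  keep <- from != to
  from <- from[keep]; to <- to[keep]
  key <- pair_key(from, to)
  first <- !duplicated(key)
  from <- from[first]; to <- to[first]
  if (is.null(nodes)) nodes <- sort(unique(c(from, to)))
  assert_that(!anyDuplicated(nodes), "node symbols must be unique")
  extra <- setdiff(unique(c(from, to)), nodes)
  assert_that(length(extra) == 0, sprintf(
    "edge list mentions nodes outside the node list: %s",
    paste(head(extra, 5), collapse = ", ")
  ))
  structure(
    list(nodes = nodes, edges = cbind(from, to)),
    class = "drugsyn_ppi"
  )
}

#' @export
print.drugsyn_ppi <- function(x, ...) {
  cat(sprintf("<drugsyn_ppi> %d nodes, %d edges\n", length(x$nodes), nrow(x$edges)))
  invisible(x)
}

ppi_adjacency_list <- function(network) {
  idx <- seq_along(network$nodes)
  names(idx) <- network$nodes
  nbrs <- vector("list", length(idx))
  for (i in idx) nbrs[[i]] <- integer(0)
  if (nrow(network$edges) > 0) {
    a <- unname(idx[network$edges[, 1]])
    b <- unname(idx[network$edges[, 2]])
    for (e in seq_along(a)) {
      nbrs[[a[e]]] <- c(nbrs[[a[e]]], b[e])
      nbrs[[b[e]]] <- c(nbrs[[b[e]]], a[e])
    }
    nbrs <- lapply(nbrs, sort)
  }
  nbrs
}

#' Configuration for node2vec embedding
#'
#' @param p return parameter: weight `1/p` for stepping back to the previous
#'   node (default 1).
#' @param q in-out parameter: weight `1/q` for moving away from the previous
#'   node's neighbourhood (default 1).
#' @param walks_per_node number of walks started at every node (default 10).
#' @param walk_length maximum walk length in nodes (default 80).
#' @param window skip-gram context window (default 10).
#' @param dim embedding dimensionality (default 128).
#' @param negative negative samples per positive pair (default 5).
#' @param epochs skip-gram passes over the walk corpus (default 5).
#' @param alpha initial skip-gram learning rate (default 0.025).
#' @param seed RNG seed for walks and training (default 1).
#' @return list of class `drugsyn_walk_config`.
#' @export
walk_config <- function(p = 1, q = 1, walks_per_node = 10, walk_length = 80,
                        window = 10, dim = 128, negative = 5, epochs = 5,
                        alpha = 0.025, seed = 1) {
  assert_that(p > 0 && q > 0, "p and q must be positive")
  assert_that(walks_per_node >= 1 && walk_length >= 1, "walk counts must be positive")
  structure(
    list(
      p = p, q = q, walks_per_node = walks_per_node,
      walk_length = walk_length, window = window, dim = dim,
      negative = negative, epochs = epochs, alpha = alpha, seed = seed
    ),
    class = "drugsyn_walk_config"
  )
}

# Second-order transition distribution: from state (prev t, current v),
# candidate x is weighted 1/p if x == t, 1 if x adjacent to t, 1/q otherwise.
biased_step_probs <- function(nbrs, prev, current, p, q) {
  cand <- nbrs[[current]]
  if (length(cand) == 0) return(NULL)
  if (is.na(prev)) {
    w <- rep(1, length(cand))
  } else {
    w <- ifelse(cand == prev, 1 / p,
      ifelse(cand %in% nbrs[[prev]], 1, 1 / q)
    )
  }
  w / sum(w)
}

#' Generate second-order biased random walks
#'
#' Starts `walks_per_node` walks at every node of the network. Each step
#' samples the next node from the node2vec second-order distribution;
#' walks stop early at dead ends, so isolated nodes yield length-1 walks.
#'
#' @param network a `drugsyn_ppi`.
#' @param config a [walk_config()].
#' @return list of integer vectors (1-based node indices into
#'   `network$nodes`), grouped walk-by-walk.
#' @export
generate_biased_walks <- function(network, config) {
  n <- length(network$nodes)
  assert_that(n > 0, "network has no nodes")
  nbrs <- ppi_adjacency_list(network)
  withr_seed(config$seed, {
    # shuffled start order per round, as in node2vec
    starts <- unlist(lapply(seq_len(config$walks_per_node),
      function(r) sample.int(n)))
    biased_walks_cpp(nbrs, starts, config$walk_length, config$p, config$q)
  })
}

#' Train skip-gram embeddings on a walk corpus
#'
#' Fits word2vec-style skip-gram vectors with negative sampling by
#' single-threaded stochastic gradient descent, so results are exactly
#' reproducible for a fixed seed.
#'
#' @param walks list of integer node-index vectors from
#'   [generate_biased_walks()].
#' @param network the `drugsyn_ppi` the walks were generated on.
#' @param config a [walk_config()].
#' @return A node-embedding table: numeric matrix with one row per network
#'   node (rownames = gene symbols) and `config$dim` columns.
#' @export
train_skipgram <- function(walks, network, config) {
  n <- length(network$nodes)
  covered <- sort(unique(unlist(walks)))
  missing <- setdiff(seq_len(n), covered)
  assert_that(length(missing) == 0, sprintf(
    "node(s) absent from every walk: %s",
    paste(head(network$nodes[missing], 5), collapse = ", ")
  ))
  emb <- withr_seed(config$seed, skipgram_train_cpp(
    walks, n, config$dim, config$window, config$negative,
    config$epochs, config$alpha
  ))
  check_finite(emb, "skip-gram embeddings")
  rownames(emb) <- network$nodes
  emb
}

#' Embed a PPI network with node2vec
#'
#' Composition of [generate_biased_walks()] and [train_skipgram()], with an
#' on-disk cache keyed by a hash of the network and configuration so that
#' repeated calls are bitwise identical and free.
#'
#' @inheritParams generate_biased_walks
#' @param cache_dir directory for cached embeddings, or `NULL` to disable
#'   caching. Defaults to `tools::R_user_dir("drugsyn", "cache")`.
#' @return node-embedding matrix (genes x dim), rownames = gene symbols.
#' @export
embed_network <- function(network, config = walk_config(), cache_dir = NULL) {
  cache_file <- NULL
  if (!identical(cache_dir, FALSE)) {
    if (is.null(cache_dir)) cache_dir <- tools::R_user_dir("drugsyn", "cache")
    key <- rlang::hash(list(network$nodes, network$edges, unclass(config)))
    cache_file <- file.path(cache_dir, paste0("node2vec-", key, ".rds"))
    if (file.exists(cache_file)) return(readRDS(cache_file))
  }
  walks <- generate_biased_walks(network, config)
  emb <- train_skipgram(walks, network, config)
  isolated <- vapply(ppi_adjacency_list(network), length, integer(1)) == 0
  if (any(isolated)) {
    warn(sprintf(
      "%d isolated node(s) received zero embeddings: %s",
      sum(isolated), paste(head(network$nodes[isolated], 5), collapse = ", ")
    ))
    emb[isolated, ] <- 0
  }
  if (!is.null(cache_file)) {
    dir.create(dirname(cache_file), recursive = TRUE, showWarnings = FALSE)
    saveRDS(emb, cache_file)
  }
  emb
}

#' Align a node-embedding table with an expression gene order
#'
#' Genes present in the expression panel but absent from the PPI network
#' receive zero vectors with a warning, preserving the shared gene order
#' contract between the expression matrix and the attention tokens.
#'
#' @param embedding matrix from [embed_network()].
#' @param genes character vector giving the required gene order.
#' @return matrix with `length(genes)` rows in the requested order.
#' @export
align_embedding <- function(embedding, genes) {
  out <- matrix(0, length(genes), ncol(embedding),
    dimnames = list(genes, NULL))
  hit <- intersect(genes, rownames(embedding))
  out[hit, ] <- embedding[hit, ]
  missing <- setdiff(genes, rownames(embedding))
  if (length(missing) > 0) {
    warn(sprintf(
      "%d gene(s) missing from the PPI embedding were zero-filled: %s",
      length(missing), paste(head(missing, 5), collapse = ", ")
    ))
  }
  out
}
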