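path_network <- function() {
  # A - B - C path
  ppi_network(c("A", "B"), c("B", "C"))
}

test_that("second-order transition weights follow the return/in-out rule", {
  net <- path_network()
  nbrs <- drugsyn:::ppi_adjacency_list(net)
  # at B having come from A, p = q = 1: back to A or on to C, 1/2 each
  pr <- drugsyn:::biased_step_probs(nbrs, prev = 1, current = 2, p = 1, q = 1)
  expect_equal(unname(pr), c(0.5, 0.5))

  # q = 0.5 doubles the weight of moving away: P(A) = 1/3, P(C) = 2/3
  pr2 <- drugsyn:::biased_step_probs(nbrs, prev = 1, current = 2, p = 1, q = 0.5)
  expect_equal(unname(pr2), c(1 / 3, 2 / 3))

  # triangle: all transitions strictly positive
  tri <- ppi_network(c("A", "B", "C"), c("B", "C", "A"))
  tn <- drugsyn:::ppi_adjacency_list(tri)
  for (prev in 1:3) {
    for (cur in setdiff(1:3, prev)) {
      pr3 <- drugsyn:::biased_step_probs(tn, prev, cur, p = 2, q = 0.7)
      expect_true(all(pr3 > 0))
    }
  }
})

test_that("transition distributions sum to one on random small graphs (enumeration oracle)", {
  set.seed(11)
  for (rep in 1:5) {
    n <- sample(4:10, 1)
    A <- matrix(0, n, n)
    for (e in 1:(2 * n)) {
      ij <- sample(n, 2)
      A[ij[1], ij[2]] <- 1
      A[ij[2], ij[1]] <- 1
    }
    nodes <- LETTERS[1:n]
    idx <- which(A == 1 & upper.tri(A), arr.ind = TRUE)
    net <- ppi_network(nodes[idx[, 1]], nodes[idx[, 2]], nodes = nodes)
    nbrs <- drugsyn:::ppi_adjacency_list(net)
    p <- runif(1, 0.3, 3)
    q <- runif(1, 0.3, 3)
    for (v in 1:n) {
      for (t in nbrs[[v]]) {
        pr <- drugsyn:::biased_step_probs(nbrs, t, v, p, q)
        expect_equal(sum(pr), 1, tolerance = 1e-12)
        expect_equal(unname(pr), unname(oracle_step_probs(A, t, v, p, q)))
      }
    }
  }
})

test_that("biased walks start everywhere, follow edges, and stop at dead ends", {
  fx <- tiny_fixture()
  cfgw <- walk_config(walks_per_node = 3, walk_length = 12, seed = 2)
  walks <- generate_biased_walks(fx$ppi, cfgw)
  n <- length(fx$ppi$nodes)
  expect_length(walks, 3 * n)
  starts <- vapply(walks, `[`, integer(1), 1)
  expect_equal(sort(unique(starts)), 1:n)

  nbrs <- drugsyn:::ppi_adjacency_list(fx$ppi)
  for (w in walks[1:20]) {
    if (length(w) > 1) {
      for (s in 2:length(w)) {
        expect_true(w[s] %in% nbrs[[w[s - 1]]])
      }
    }
  }

  # determinism per seed
  expect_identical(walks, generate_biased_walks(fx$ppi, cfgw))

  # isolated node: walks of length 1, no error
  iso <- ppi_network(c("A"), c("B"), nodes = c("A", "B", "Z"))
  wi <- generate_biased_walks(iso, walk_config(walks_per_node = 1,
    walk_length = 5, seed = 1))
  z <- which(iso$nodes == "Z")
  lens <- vapply(wi, length, integer(1))
  expect_equal(lens[vapply(wi, `[`, integer(1), 1) == z], 1L)
})

test_that("skip-gram training is deterministic, respects dim, and separates cliques", {
  # two 6-cliques joined by one bridge edge
  nodes <- c(paste0("L", 1:6), paste0("R", 1:6))
  edges <- rbind(
    t(combn(paste0("L", 1:6), 2)),
    t(combn(paste0("R", 1:6), 2)),
    c("L1", "R1")
  )
  net <- ppi_network(edges[, 1], edges[, 2], nodes = nodes)
  cfgw <- walk_config(dim = 12, walks_per_node = 8, walk_length = 30,
    epochs = 3, seed = 9)
  walks <- generate_biased_walks(net, cfgw)
  emb <- train_skipgram(walks, net, cfgw)
  expect_equal(dim(emb), c(12, 12))
  expect_true(all(is.finite(emb)))

  # same seed -> identical table
  expect_identical(emb, train_skipgram(walks, net, cfgw))

  # community separation: within-clique cosine similarity beats cross-clique
  cossim <- function(a, b) sum(a * b) / sqrt(sum(a^2) * sum(b^2))
  left <- emb[1:6, ]; right <- emb[7:12, ]
  within <- c(
    combn(1:6, 2, function(ij) cossim(left[ij[1], ], left[ij[2], ])),
    combn(1:6, 2, function(ij) cossim(right[ij[1], ], right[ij[2], ]))
  )
  cross <- as.vector(outer(1:6, 1:6, Vectorize(function(i, j)
    cossim(left[i, ], right[j, ]))))
  expect_gt(mean(within), mean(cross))

  # a node missing from every walk is reported by name
  expect_error(
    train_skipgram(walks, ppi_network(edges[, 1], edges[, 2],
      nodes = c(nodes, "GHOST")), cfgw),
    "GHOST"
  )
})

test_that("embed_network caches bitwise-identical tables and zero-fills missing genes", {
  fx <- tiny_fixture()
  cfgw <- walk_config(dim = 8, walks_per_node = 2, walk_length = 10,
    epochs = 1, seed = 3)
  cache_dir <- tempfile("n2vcache")
  t1 <- embed_network(fx$ppi, cfgw, cache_dir = cache_dir)
  expect_equal(nrow(t1), length(fx$ppi$nodes))
  t2 <- embed_network(fx$ppi, cfgw, cache_dir = cache_dir)
  expect_identical(t1, t2)
  expect_length(list.files(cache_dir), 1)

  # genes absent from the network get zero vectors with a warning
  genes <- c(rownames(t1), "ABSENT1")
  expect_warning(al <- align_embedding(t1, genes), "ABSENT1")
  expect_equal(unname(al["ABSENT1", ]), rep(0, 8))
  expect_equal(al[rownames(t1), ], t1[, , drop = FALSE],
    ignore_attr = TRUE)
})
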