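test_that("the classifier forward pass follows the ReLU chain and exposes hidden layers", {
  params <- init_classifier(input_dim = 20, hidden = c(12, 8, 5), seed = 2)
  f1 <- rnorm(14)
  f2 <- rnorm(6)
  out <- classifier_forward(f1, f2, params)
  expect_length(out$logits, 2)
  expect_length(out$hidden, 3)
  expect_length(out$hidden[[1]], 12)
  expect_length(out$hidden[[3]], 5)

  # eval-mode determinism
  expect_identical(out$logits, classifier_forward(f1, f2, params)$logits)

  # zero parameters give zero logits
  zero <- params
  zero$W <- lapply(zero$W, function(w) w * 0)
  expect_equal(classifier_forward(f1, f2, zero)$logits, c(0, 0))

  expect_error(classifier_forward(f1, rnorm(3), params), "width")
})

test_that("softmax probabilities match closed forms and survive huge logits", {
  expect_equal(predict_proba(c(0, 0)), c(0.5, 0.5))
  expect_equal(predict_proba(c(log(3), 0)), c(0.75, 0.25), tolerance = 1e-12)

  # overflow-safe: reference computed in log space
  p <- predict_proba(c(1000, 0))
  expect_true(all(is.finite(p)))
  expect_equal(p[1], 1, tolerance = 1e-12)
  expect_equal(sum(p), 1)

  # matrix input: every row sums to one
  set.seed(3)
  P <- predict_proba(matrix(rnorm(20, sd = 50), 10, 2))
  expect_lt(max(abs(rowSums(P) - 1)), 1e-9)
  expect_true(all(P > 0))
})

test_that("cross-entropy matches closed forms and reduces by the batch mean", {
  expect_equal(cross_entropy(c(0, 1), 1L), 0, tolerance = 1e-10)
  expect_equal(cross_entropy(c(0.5, 0.5), 0L), log(2), tolerance = 1e-12)
  expect_equal(cross_entropy(c(0.5, 0.5), 1L), log(2), tolerance = 1e-12)

  set.seed(5)
  P <- predict_proba(matrix(rnorm(16), 8, 2))
  y <- sample(0:1, 8, replace = TRUE)
  manual <- mean(vapply(1:8, function(i) -log(P[i, y[i] + 1]), numeric(1)))
  expect_equal(cross_entropy(P, y), manual, tolerance = 1e-12)

  # hard zero probabilities are floored, not -Inf
  expect_true(is.finite(cross_entropy(c(1, 0), 1L)))
})

test_that("analytic gradients of the full network match numeric differentiation", {
  fx <- tiny_fixture()
  cfg <- model_config(
    gcn_dims = c(78, 10, 6), chem_dim = 16, cell_hidden = c(12, 10, 8),
    heads = 2, d_k = 3, ffn_dim = 5, n_layers = 2, pool_dim = 7,
    clf_hidden = c(9, 6, 4), dropout = 0, seed = 4
  )
  bk <- chem_backend(dim = 16)
  P <- matrix(rnorm(20 * 6, sd = 0.3), 20, 6,
    dimnames = list(setdiff(names(fx$expression), "cell_line"), NULL))
  bundle <- drugsyn:::prepare_model_data(fx$triplets, fx$expression, P, cfg,
    backend = bk, zscore_cell_lines = unique(fx$triplets$cell_line))
  params <- init_model_params(cfg, 20)
  rows <- 1:10
  res <- drugsyn:::model_batch(params, bundle, rows, cfg, need_grads = TRUE)
  loss_at <- function(p) drugsyn:::model_batch(p, bundle, rows, cfg)$loss

  get_leaf <- function(l, path) {
    for (k in path) l <- l[[k]]
    l
  }
  set_leaf <- function(l, path, v) {
    if (length(path) == 1) {
      l[[path[[1]]]] <- v
    } else {
      l[[path[[1]]]] <- set_leaf(l[[path[[1]]]], path[-1], v)
    }
    l
  }
  paths <- list(
    c("gcn", "W0"), c("gcn", "W1"),
    c("enc", 1, "attn", "heads", 1, "Wq"), c("enc", 2, "attn", "heads", 2, "Wv"),
    c("enc", 1, "attn", "Wo"), c("enc", 2, "W1"), c("enc", 1, "ln2", "g"),
    c("pool", "Wp"), c("cell", "W", 1), c("cell", "b", 2),
    c("clf", "W", 1), c("clf", "W", 4), c("clf", "b", 3)
  )
  eps <- 1e-5
  set.seed(10)
  for (pth in paths) {
    leaf <- get_leaf(params, pth)
    gleaf <- get_leaf(res$grads, pth)
    for (i in sample(length(leaf), min(2, length(leaf)))) {
      lp <- leaf; lp[i] <- lp[i] + eps
      lm <- leaf; lm[i] <- lm[i] - eps
      num <- (loss_at(set_leaf(params, as.list(pth), lp)) -
        loss_at(set_leaf(params, as.list(pth), lm))) / (2 * eps)
      rel <- abs(num - gleaf[i]) / max(1e-8, abs(num) + abs(gleaf[i]))
      expect_lt(rel, 1e-4)
    }
  }
})

test_that("screening enumerates the full drug x cell-line grid", {
  fx <- tiny_fixture()
  model <- init_model(fx$expression, tiny_embedding(), tiny_config(),
    backend = tiny_backend())
  lib <- fx$smiles_lib[1:3, c("drug", "smiles")]
  cells <- fx$expression$cell_line[1:2]
  scr <- enumerate_screen(model, "Q", "CCO", lib, cells)
  expect_equal(nrow(scr), 6)
  expect_true(all(scr$prob_synergy >= 0 & scr$prob_synergy <= 1))

  one <- enumerate_screen(model, "Q", "CCO", lib[1, ], cells[1])
  expect_equal(nrow(one), 1)
  none <- enumerate_screen(model, "Q", "CCO", lib, character(0))
  expect_equal(nrow(none), 0)
})
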