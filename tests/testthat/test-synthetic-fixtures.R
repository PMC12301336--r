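test_that("every library molecule parses and both scaffold classes are present", {
  lib <- make_smiles_library(n_drugs = length(drugsyn:::SMILES_LIBRARY), seed = 1)
  for (i in seq_len(nrow(lib))) {
    g <- smiles_to_graph(lib$smiles[i])
    expect_gte(nrow(g$A), 1)
    expect_equal(any(g$aromatic), lib$aromatic[i])
  }
  expect_gt(sum(lib$aromatic), 10)
  expect_gt(sum(!lib$aromatic), 10)

  # seeded selection is reproducible and capacity is enforced
  expect_identical(make_smiles_library(10, seed = 2),
    make_smiles_library(10, seed = 2))
  expect_error(make_smiles_library(10000), "capacity")
})

test_that("the preferential-attachment generator yields (n-m)*m edges, connected and skewed", {
  net <- make_synthetic_ppi(50, attachment = 2, seed = 3)
  expect_length(net$nodes, 50)
  expect_equal(nrow(net$edges), (50 - 2) * 2)

  g <- igraph::graph_from_edgelist(net$edges, directed = FALSE)
  g <- igraph::add_vertices(g, 50 - igraph::vcount(g))
  expect_true(igraph::is_connected(
    igraph::graph_from_data_frame(as.data.frame(net$edges), directed = FALSE,
      vertices = data.frame(name = net$nodes))
  ))

  # right-skewed degree distribution at n = 200
  big <- make_synthetic_ppi(200, attachment = 2, seed = 5)
  gb <- igraph::graph_from_data_frame(as.data.frame(big$edges),
    directed = FALSE, vertices = data.frame(name = big$nodes))
  deg <- igraph::degree(gb)
  expect_gt(max(deg), 3 * median(deg))

  # no self-loops or duplicate edges
  expect_false(any(net$edges[, 1] == net$edges[, 2]))
  key <- paste(pmin(net$edges[, 1], net$edges[, 2]),
    pmax(net$edges[, 1], net$edges[, 2]))
  expect_false(any(duplicated(key)))
})

test_that("synthetic expression carries the planted signature shift", {
  cells <- sprintf("CL%02d", 1:12)
  ex <- make_synthetic_expression(cells, n_genes = 60, seed = 7)
  expect_equal(dim(ex), c(12, 61)) # cell_line column + 60 genes
  sig_cl <- attr(ex, "signature_cell_lines")
  sig_genes <- attr(ex, "signature_genes")
  expect_length(sig_cl, 6)
  expect_length(sig_genes, 10)

  m <- as.matrix(ex[, sig_genes])
  rownames(m) <- ex$cell_line
  expect_equal(mean(m[sig_cl, ]), 2, tolerance = 0.5)
  expect_equal(mean(m[setdiff(cells, sig_cl), ]), 0, tolerance = 0.5)

  expect_identical(ex, make_synthetic_expression(cells, 60, seed = 7))
})

test_that("planted labels follow the XOR rule exactly at zero noise", {
  cfg <- fixture_config(n_drugs = 10, n_cell_lines = 8, n_genes = 20,
    n_triplets = 200, noise = 0, seed = 13)
  fx <- make_fixture_dataset(cfg)
  expect_equal(fx$triplets$label, fx$rule$true_label)
  expect_false(any(fx$rule$flipped))

  # recompute the rule independently from the emitted components
  arom <- setNames(fx$smiles_lib$aromatic, fx$smiles_lib$drug)
  sig <- fx$triplets$cell_line %in% attr(fx$expression, "signature_cell_lines")
  manual <- as.integer(xor(arom[fx$triplets$drug_a] & arom[fx$triplets$drug_b], sig))
  expect_equal(fx$triplets$label, unname(manual))

  # class balance within the stated band
  expect_gte(mean(fx$triplets$label), 0.4)
  expect_lte(mean(fx$triplets$label), 0.6)

  # scores are consistent with the thresholding pipeline
  relabelled <- label_by_threshold(fx$triplets[, -which(names(fx$triplets) == "label")],
    quiet = TRUE)
  expect_equal(relabelled$label, fx$triplets$label)
})

test_that("flip noise corrupts the stated fraction of labels", {
  cfg <- fixture_config(n_drugs = 12, n_cell_lines = 10, n_genes = 20,
    n_triplets = 400, noise = 0.25, seed = 17)
  fx <- make_fixture_dataset(cfg)
  flip_rate <- mean(fx$triplets$label != fx$rule$true_label)
  expect_equal(flip_rate, 0.25, tolerance = 0.06)
  expect_identical(make_fixture_dataset(cfg)$triplets, fx$triplets)
})

test_that("the AUROC ceiling formula matches a simulation of the optimal scorer", {
  set.seed(19)
  n <- 20000
  rule <- sample(0:1, n, replace = TRUE)
  noisy <- ifelse(runif(n) < 0.1, 1L - rule, rule)
  sim <- compute_metrics(noisy, rule)$auroc # optimal scorer = the rule itself
  expect_equal(planted_rule_ceiling(0.1), 0.9)
  expect_equal(sim, 0.9, tolerance = 0.01)
})

test_that("fixture files round-trip through the real loaders", {
  fx <- tiny_fixture()
  dir <- tempfile("fixdir")
  write_fixture_files(fx, dir)
  expect_setequal(list.files(dir), c("combinations.csv", "expression.tsv",
    "ppi_edges.tsv", "tissue_map.tsv"))

  rec <- load_combination_table(file.path(dir, "combinations.csv"))
  expect_equal(nrow(rec), nrow(fx$triplets))
  ex <- load_expression_matrix(file.path(dir, "expression.tsv"))
  expect_equal(dim(ex), dim(fx$expression))
  net <- load_ppi_network(file.path(dir, "ppi_edges.tsv"),
    nodes = setdiff(names(ex), "cell_line"))
  expect_equal(nrow(net$edges), nrow(fx$ppi$edges))
  expect_length(net$nodes, 20)
})
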