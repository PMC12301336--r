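fake_records <- function(seed = 1, va = 3, vb = 2, ng = 10, layers = 2, heads = 2) {
  set.seed(seed)
  T_ <- va + vb + ng
  roles <- tibble::tibble(
    role = rep(c("atomA", "atomB", "gene"), c(va, vb, ng)),
    label = c(paste0("C:", 1:va), paste0("N:", 1:vb), sprintf("G%02d", 1:ng)),
    index = c(1:va, 1:vb, 1:ng)
  )
  out <- list()
  for (l in 1:layers) {
    for (h in 1:heads) {
      S <- matrix(runif(T_ * T_), T_, T_)
      S <- S / rowSums(S)
      out[[length(out) + 1]] <- drugsyn:::new_attention_record(l, h, S, roles)
    }
  }
  out
}

test_that("column min-max normalization is idempotent and shift/scale invariant", {
  expect_equal(normalize_attention_columns(matrix(c(1, 3), 2, 1)),
    matrix(c(0, 1), 2, 1))
  expect_equal(normalize_attention_columns(matrix(c(2, 2), 2, 1)),
    matrix(c(0, 0), 2, 1))

  m <- matrix(c(0, 0.4, 1, 0.2, 0.9, 0), 3, 2)
  m[, 1] <- c(0, 0.5, 1)
  n1 <- normalize_attention_columns(m)
  expect_equal(normalize_attention_columns(n1), n1)
  expect_equal(n1[, 1], m[, 1]) # already spanning [0,1]

  set.seed(2)
  r <- matrix(runif(12), 4, 3)
  shifted <- sweep(sweep(r, 2, c(2, -1, 5), "*"), 2, c(1, 3, -2), "+")
  shifted[, 2] <- -shifted[, 2] # keep orientation positive
  scaled <- sweep(sweep(r, 2, c(2, 1, 5), "*"), 2, c(1, 3, -2), "+")
  expect_equal(normalize_attention_columns(scaled),
    normalize_attention_columns(r), tolerance = 1e-12)
})

test_that("attention slicing restricts roles, labels rows, and aggregates heads", {
  recs <- fake_records()
  v <- slice_attention(recs, "atomA", "gene")
  expect_equal(dim(v$matrix), c(3, 10))
  expect_equal(rownames(v$matrix), paste0("C:", 1:3))
  expect_equal(colnames(v$matrix), sprintf("G%02d", 1:10))
  expect_equal(v$layer, 2) # defaults to the final layer

  vab <- slice_attention(recs, "atomA", "atomB")
  expect_equal(dim(vab$matrix), c(3, 2))

  per <- slice_attention(recs, "atomA", "gene", head_aggregation = "per_head")
  expect_length(per, 2)
  manual_mean <- (per[[1]]$matrix + per[[2]]$matrix) / 2
  expect_equal(v$matrix, manual_mean, tolerance = 1e-12)

  # mean of identical heads equals any single head
  recs_same <- fake_records()
  recs_same[[4]]$scores <- recs_same[[3]]$scores
  v_same <- slice_attention(recs_same, "atomB", "gene")
  expect_equal(v_same$matrix,
    slice_attention(recs_same, "atomB", "gene",
      head_aggregation = "per_head")[[1]]$matrix,
    tolerance = 1e-12)

  expect_error(slice_attention(recs, "nosuchrole", "gene"), "nosuchrole")
})

test_that("normalization is applied after slicing, not before", {
  recs <- fake_records(seed = 9)
  v <- normalize_view(slice_attention(recs, "atomA", "gene"))
  # every column of the slice spans [0, 1] exactly
  expect_equal(unname(apply(v$matrix, 2, min)), rep(0, 10))
  expect_equal(unname(apply(v$matrix, 2, max)), rep(1, 10))

  # normalizing the full matrix first then slicing gives different values
  full <- slice_attention(recs, "atomA", "gene")
  full_norm <- normalize_attention_columns(
    (recs[[3]]$scores + recs[[4]]$scores) / 2
  )[1:3, 6:15]
  expect_false(isTRUE(all.equal(v$matrix, full_norm, check.attributes = FALSE)))
})

test_that("gene ranking is max-aggregated over atoms and stable under atom permutation", {
  recs <- fake_records(seed = 5)
  # plant a dominant gene column in every final-layer head
  for (k in 3:4) recs[[k]]$scores[1:3, 8] <- 5
  v <- slice_attention(recs, "atomA", "gene")
  top <- top_attended_genes(v, 3)
  expect_equal(top$gene[1], "G03") # gene tokens start at index 6 -> column 3
  expect_equal(top$score[1], 1)
  expect_warning(top_attended_genes(normalize_view(v), 3), "degenerate")

  expect_equal(nrow(top_attended_genes(v, 0)), 0)
  expect_equal(nrow(top_attended_genes(v, 99)), 10) # truncated to gene count

  # permuting atom rows does not change the ranking
  v_perm <- v
  v_perm$matrix <- v$matrix[c(3, 1, 2), ]
  expect_equal(top_attended_genes(v_perm, 5), top_attended_genes(v, 5))

  expect_error(top_attended_genes(slice_attention(recs, "atomA", "atomB")),
    "gene")
})

test_that("hidden-embedding projection is seeded, row-aligned, and separation-preserving", {
  set.seed(31)
  blob1 <- matrix(rnorm(20 * 64), 20, 64)
  blob2 <- matrix(rnorm(20 * 64), 20, 64)
  blob2[, 1:10] <- blob2[, 1:10] + 8
  act <- rbind(blob1, blob2)
  labels <- rep(0:1, each = 20)
  proj <- project_hidden_embeddings(act, labels, seed = 3)
  expect_equal(nrow(proj), 40)
  expect_identical(proj, project_hidden_embeddings(act, labels, seed = 3))

  skip_if_not_installed("cluster")
  sil <- cluster::silhouette(labels + 1, dist(as.matrix(proj[, c("dim1", "dim2")])))
  expect_gt(mean(sil[, "sil_width"]), 0.5)

  expect_error(project_hidden_embeddings(act[1:5, ], labels[1:5]), "10 rows")
})

test_that("trained models expose attention and hidden activations for real triplets", {
  fit <- tiny_model()
  fx <- tiny_fixture()
  trip <- fx$triplets[1, ]
  recs <- attention_scores(fit, trip)
  expect_length(recs, 4)
  va <- sum(recs[[1]]$roles$role == "atomA")
  expect_equal(va, nrow(smiles_to_graph(trip$smiles_a)$A))
  expect_true(all(abs(rowSums(recs[[1]]$scores) - 1) < 1e-6))

  v <- slice_attention(recs, "atomA", "gene")
  expect_equal(ncol(v$matrix), 20)
  expect_s3_class(tidy(v), "tbl_df")

  h512 <- hidden_activations(fit, fx$triplets[1:12, ], width = 512)
  expect_equal(dim(h512), c(12, 16)) # tiny config's first hidden width
  h32 <- hidden_activations(fit, fx$triplets[1:12, ], width = 32)
  expect_equal(ncol(h32), 4) # tiny config's third hidden width

  tf <- tempfile(fileext = ".tsv")
  write_attention_view(normalize_view(v), tf)
  expect_gt(nrow(readr::read_tsv(tf, show_col_types = FALSE)), 0)
})
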