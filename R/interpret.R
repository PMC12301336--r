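# Attention-score views and hidden-embedding projections.

#' Min-max normalize the columns of an attention matrix
#'
#' Each column is mapped by `(x - min) / (max - min)`. Constant columns are
#' mapped to zero with an informational note, since they carry no contrast.
#' The transform is idempotent and invariant to per-column scale and shift.
#'
#' @param m numeric matrix.
#' @param quiet suppress the constant-column note.
#' @return matrix of the same shape with every column in `[0, 1]`.
#' @export
normalize_attention_columns <- function(m, quiet = TRUE) {
  check_finite(m, "attention matrix")
  rng <- apply(m, 2, range)
  span <- rng[2, ] - rng[1, ]
  flat <- span == 0
  if (any(flat) && !quiet) {
    inform(sprintf("%d constant column(s) normalized to zero", sum(flat)))
  }
  span[flat] <- 1
  out <- sweep(sweep(m, 2, rng[1, ], "-"), 2, span, "/")
  out[, flat] <- 0
  out
}

#' Extract attention scores for a triplet
#'
#' Runs the trained model's encoder stack over the triplet's token matrix in
#' evaluation mode and returns the raw attention records of every layer and
#' head.
#'
#' @param model a `drugsyn_model` whose variant includes the encoder stack.
#' @param triplet one-row triplet tibble.
#' @param expression optional expression table for unseen cell lines.
#' @return list of `drugsyn_attention` records (`n_layers * heads`).
#' @export
attention_scores <- function(model, triplet, expression = NULL) {
  assert_that(uses_encoder(model$config),
    "attention scores require a variant with the graph-trans encoder")
  assert_that(nrow(triplet) == 1, "attention_scores expects a single triplet")
  bundle <- prediction_bundle(model, triplet, expression)
  res <- model_batch(model$params, bundle, 1L, model$config,
    train_mode = FALSE, collect = TRUE)
  res$records
}

#' Slice attention records into a labelled view
#'
#' Restricts the score matrices to the requested query and key roles
#' (`"atomA"`, `"atomB"`, `"gene"`), optionally averaging heads, and
#' attaches row and column labels (atom element:index or gene symbol).
#' By default the final encoder layer is used with heads averaged; both
#' knobs are exposed because the attention analysis layer/head choice is a
#' reporting convention, not part of the model.
#'
#' @param records list of `drugsyn_attention` from [attention_scores()] or
#'   [graph_trans_pool()].
#' @param query_role,key_role role selectors.
#' @param head_aggregation `"mean"` or `"per_head"`.
#' @param layer encoder layer to use (default: last available).
#' @return A `drugsyn_attention_view` (single view) or a list of views when
#'   `head_aggregation = "per_head"`. Each view holds `matrix` (labelled),
#'   `query_role`, `key_role`, `layer`, `head` (`NA` for mean), and
#'   `normalized` (FALSE).
#' @export
slice_attention <- function(records, query_role, key_role,
                            head_aggregation = c("mean", "per_head"),
                            layer = NULL) {
  head_aggregation <- match.arg(head_aggregation)
  layers <- vapply(records, function(r) r$layer, integer(1))
  if (is.null(layer)) layer <- max(layers)
  recs <- records[layers == layer]
  assert_that(length(recs) > 0, sprintf("no attention records for layer %s", layer))
  roles <- recs[[1]]$roles
  assert_that(!is.null(roles), "attention records carry no role index")
  qi <- which(roles$role == query_role)
  ki <- which(roles$role == key_role)
  assert_that(length(qi) > 0, sprintf("no tokens with query role '%s'", query_role))
  assert_that(length(ki) > 0, sprintf("no tokens with key role '%s'", key_role))

  slice_one <- function(r, head) {
    m <- r$scores[qi, ki, drop = FALSE]
    rownames(m) <- roles$label[qi]
    colnames(m) <- roles$label[ki]
    structure(
      list(matrix = m, query_role = query_role, key_role = key_role,
        layer = layer, head = head, normalized = FALSE),
      class = "drugsyn_attention_view"
    )
  }
  if (head_aggregation == "per_head") {
    return(lapply(recs, function(r) slice_one(r, r$head)))
  }
  avg <- Reduce(`+`, lapply(recs, function(r) r$scores)) / length(recs)
  slice_one(list(scores = avg), NA_integer_)
}

#' @export
print.drugsyn_attention_view <- function(x, ...) {
  cat(sprintf(
    "<drugsyn_attention_view> %s x %s, layer %d, head %s, %d x %d%s\n",
    x$query_role, x$key_role, x$layer,
    ifelse(is.na(x$head), "mean", x$head),
    nrow(x$matrix), ncol(x$matrix),
    if (x$normalized) ", column-normalized" else ""
  ))
  invisible(x)
}

#' Column-normalize an attention view
#'
#' Applies [normalize_attention_columns()] to the sliced matrix. The module
#' normalizes after slicing (heatmap scope), so normalizing a slice is not
#' the same as slicing a normalized full matrix unless slices keep whole
#' columns.
#'
#' @param view a `drugsyn_attention_view`.
#' @return the view with `matrix` normalized and `normalized = TRUE`.
#' @export
normalize_view <- function(view) {
  view$matrix <- normalize_attention_columns(view$matrix)
  view$normalized <- TRUE
  view
}

#' @describeIn slice_attention long-format tibble of a view
#'   (query label, key label, score).
#' @param x a `drugsyn_attention_view`.
#' @param ... unused.
#' @method tidy drugsyn_attention_view
#' @export
tidy.drugsyn_attention_view <- function(x, ...) {
  m <- x$matrix
  tibble(
    query = rep(rownames(m), times = ncol(m)),
    key = rep(colnames(m), each = nrow(m)),
    score = as.numeric(m),
    layer = x$layer,
    head = x$head
  )
}

#' @describeIn slice_attention attention heatmap.
#' @param object a `drugsyn_attention_view`.
#' @method autoplot drugsyn_attention_view
#' @export
autoplot.drugsyn_attention_view <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$key, y = .data$query,
    fill = .data$score)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(
      x = object$key_role, y = object$query_role,
      fill = if (object$normalized) "scaled\nattention" else "attention"
    ) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
      vjust = 0.5, hjust = 1))
}

#' Rank genes by attention received from a drug's atoms
#'
#' Aggregates each gene's raw attention column by the maximum over the
#' drug's atoms (preserving sharp atom-level signals), then min-max scales
#' the aggregated scores across genes so the strongest gene reads 1.
#' Aggregation happens on the raw slice: per-column min-max normalization
#' would force every non-constant column to a maximum of exactly 1 and
#' erase the ranking. Ties break lexicographically.
#'
#' @param view an unnormalized `drugsyn_attention_view` whose key role is
#'   `"gene"`.
#' @param k number of genes to return; values above the gene count are
#'   truncated.
#' @return tibble with `gene` and `score` (scaled to `[0, 1]`), strongest
#'   first.
#' @export
top_attended_genes <- function(view, k = 10) {
  assert_that(view$key_role == "gene", "view's key role must be 'gene'")
  if (k <= 0) return(tibble(gene = character(), score = double()))
  if (view$normalized) {
    warn("ranking a column-normalized view is degenerate; pass the raw slice")
  }
  score <- apply(view$matrix, 2, max)
  rng <- range(score)
  score <- if (rng[2] > rng[1]) (score - rng[1]) / (rng[2] - rng[1]) else
    rep(0, length(score))
  out <- tibble(gene = colnames(view$matrix), score = unname(score)) |>
    arrange(desc(.data$score), .data$gene)
  head(out, min(k, nrow(out)))
}

#' Project hidden-layer activations to 2D
#'
#' Projects the 512- or 32-wide classifier hidden activations of a set of
#' triplets into two dimensions for cluster inspection. The default method
#' is a seeded principal-component projection; the `method` argument exists
#' so alternative manifold projections can be plugged in.
#'
#' @param activations numeric matrix, one row per triplet.
#' @param labels integer or factor labels, row-aligned with `activations`.
#' @param method `"pca"`.
#' @param seed integer seed (projection sign is made deterministic).
#' @return tibble with `dim1`, `dim2`, `label`, one row per input row.
#' @export
project_hidden_embeddings <- function(activations, labels,
                                      method = c("pca"), seed = 1) {
  method <- match.arg(method)
  assert_that(nrow(activations) == length(labels),
    "activations and labels must be row-aligned")
  assert_that(nrow(activations) >= 10,
    "projection needs at least 10 rows to be stable")
  keep <- apply(activations, 2, function(col) sd(col) > 0)
  assert_that(sum(keep) >= 2, "activations are constant; nothing to project")
  pc <- withr_seed(seed, prcomp(activations[, keep, drop = FALSE],
    center = TRUE, scale. = FALSE, rank. = 2))
  coords <- pc$x[, 1:2, drop = FALSE]
  # fix component signs so output is deterministic across BLAS builds
  for (j in 1:2) {
    s <- sign(coords[which.max(abs(coords[, j])), j])
    if (s < 0) coords[, j] <- -coords[, j]
  }
  tibble(dim1 = coords[, 1], dim2 = coords[, 2], label = labels)
}

#' Collect classifier hidden activations for triplets
#'
#' @param model a `drugsyn_model`.
#' @param triplets triplet tibble.
#' @param width 512 or 32 (the first and third classifier hidden layers).
#' @param expression optional expression table.
#' @return numeric matrix, one row per triplet.
#' @export
hidden_activations <- function(model, triplets, width = c(512, 32),
                               expression = NULL) {
  width <- match.arg(as.character(width[1]), c("512", "32"))
  bundle <- prediction_bundle(model, triplets, expression)
  res <- model_batch(model$params, bundle, seq_len(nrow(triplets)),
    model$config, train_mode = FALSE, collect = TRUE)
  if (width == "512") res$hidden$h512 else res$hidden$h32
}

#' Write an attention view as a flat TSV
#'
#' @param view a `drugsyn_attention_view`.
#' @param path output path.
#' @export
write_attention_view <- function(view, path) {
  readr::write_tsv(tidy(view), path)
  invisible(path)
}
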