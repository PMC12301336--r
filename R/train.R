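# End-to-end training, prediction, and screening.

#' Train the synergy prediction model
#'
#' Jointly trains the active branches (GCN, graph-trans pooling, cell-line
#' MLP, classifier) with Adam on the cross-entropy loss. The chemical-language
#' drug vectors and the node2vec PPI embeddings are precomputed and frozen.
#' Minibatches are blocked by unordered drug pair so that each pair's token
#' matrix is encoded once per batch; a held-out validation fraction drives
#' early stopping.
#'
#' @param triplets labeled triplet tibble (columns `drug_a`, `drug_b`,
#'   `smiles_a`, `smiles_b`, `cell_line`, `label`).
#' @param expression expression tibble (`cell_line` + gene columns) or
#'   matrix with cell-line rownames.
#' @param ppi_embedding node-embedding matrix aligned with the expression
#'   gene order (see [align_embedding()]).
#' @param config a [model_config()].
#' @param backend a [chem_backend()] for the drug vectors.
#' @param quiet suppress progress messages.
#' @return A `drugsyn_model`: list with `params`, `config`, `history`
#'   (per-epoch tibble), frozen data (`chem` backend tag, z-score stats,
#'   gene order, PPI embedding) and the best validation loss.
#' @export
train_model <- function(triplets, expression, ppi_embedding,
                        config = model_config(), backend = chem_backend(),
                        quiet = FALSE) {
  assert_that("label" %in% names(triplets), "triplets must carry a label column")
  assert_that(all(triplets$label %in% c(0L, 1L)), "labels must be 0/1")
  cfg <- config
  bundle <- prepare_model_data(triplets, expression, ppi_embedding, cfg,
    backend = backend,
    zscore_cell_lines = unique(triplets$cell_line))
  n <- nrow(triplets)
  n_genes <- length(bundle$genes)

  params <- init_model_params(cfg, n_genes)
  state <- adam_init(params)

  withr_seed(cfg$seed + 1L, {
    n_val <- max(1L, floor(cfg$val_fraction * n))
    val_idx <- sort(sample.int(n, n_val))
    train_idx <- setdiff(seq_len(n), val_idx)

    history <- list()
    best <- list(loss = Inf, params = params, epoch = 0L)
    wait <- 0L

    for (epoch in seq_len(cfg$epochs)) {
      batches <- pair_blocked_batches(bundle, train_idx, cfg$batch_size)
      tot_loss <- 0
      tot_n <- 0
      for (rows in batches) {
        swap <- if (cfg$augment) runif(length(rows)) < 0.5 else rep(FALSE, length(rows))
        res <- model_batch(params, bundle, rows, cfg,
          train_mode = TRUE, swap = swap, need_grads = TRUE)
        st <- adam_step(params, res$grads, state, cfg$lr)
        params <- st$params
        state <- st$state
        tot_loss <- tot_loss + res$loss * length(rows)
        tot_n <- tot_n + length(rows)
      }
      val <- model_batch(params, bundle, val_idx, cfg, train_mode = FALSE)
      history[[epoch]] <- tibble(
        epoch = epoch,
        train_loss = tot_loss / tot_n,
        val_loss = val$loss
      )
      if (!quiet) {
        inform(sprintf("epoch %3d  train %.4f  val %.4f",
          epoch, tot_loss / tot_n, val$loss))
      }
      if (val$loss < best$loss - 1e-5) {
        best <- list(loss = val$loss, params = params, epoch = epoch)
        wait <- 0L
      } else {
        wait <- wait + 1L
        if (wait >= cfg$patience) break
      }
    }
  })

  structure(
    list(
      params = best$params,
      config = cfg,
      backend = backend,
      history = dplyr::bind_rows(history),
      best_epoch = best$epoch,
      best_val_loss = best$loss,
      zstats = bundle$zstats,
      genes = bundle$genes,
      P = bundle$P,
      expression = bundle$exprz, # z-scored, cell lines x genes
      cell_lines = rownames(bundle$exprz),
      drug_tab = bundle$drug_tab
    ),
    class = "drugsyn_model"
  )
}

# Shuffle training rows with same-pair rows kept adjacent, then chunk.
pair_blocked_batches <- function(bundle, idx, batch_size) {
  pk <- paste(pmin(bundle$ia[idx], bundle$ib[idx]),
    pmax(bundle$ia[idx], bundle$ib[idx]))
  groups <- split(idx, pk)
  groups <- groups[sample.int(length(groups))]
  ordered <- unlist(groups, use.names = FALSE)
  split(ordered, ceiling(seq_along(ordered) / batch_size))
}

#' @export
print.drugsyn_model <- function(x, ...) {
  cat(sprintf(
    "<drugsyn_model> variant=%s, %d epochs (best %d, val loss %.4f), %d drugs, %d cell lines\n",
    x$config$variant, nrow(x$history), x$best_epoch, x$best_val_loss,
    nrow(x$drug_tab), length(x$cell_lines)
  ))
  invisible(x)
}

#' @describeIn train_model per-epoch loss history as a tibble.
#' @param x a `drugsyn_model`.
#' @param ... unused.
#' @method tidy drugsyn_model
#' @export
tidy.drugsyn_model <- function(x, ...) x$history

#' @describeIn train_model one-row model summary.
#' @method glance drugsyn_model
#' @export
glance.drugsyn_model <- function(x, ...) {
  tibble(
    variant = x$config$variant,
    epochs_run = nrow(x$history),
    best_epoch = x$best_epoch,
    best_val_loss = x$best_val_loss,
    n_drugs = nrow(x$drug_tab),
    n_cell_lines = length(x$cell_lines),
    n_genes = length(x$genes)
  )
}

#' @describeIn train_model training/validation loss curves.
#' @param object a `drugsyn_model`.
#' @method autoplot drugsyn_model
#' @export
autoplot.drugsyn_model <- function(object, ...) {
  df <- tidyr::pivot_longer(object$history, -"epoch",
    names_to = "series", values_to = "loss")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$epoch, y = .data$loss,
    colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "epoch", y = "cross-entropy loss", colour = NULL) +
    ggplot2::theme_minimal()
}

# Build a bundle for prediction-time triplets against a trained model.
prediction_bundle <- function(model, triplets, expression = NULL) {
  cfg <- model$config
  exprz <- model$expression
  if (!is.null(expression)) {
    em <- expression_to_matrix(expression)
    assert_that(all(colnames(em) == model$genes),
      "expression gene order must match the training panel")
    exprz <- apply_zscore(em, model$zstats)
  }
  missing_cl <- setdiff(unique(triplets$cell_line), rownames(exprz))
  assert_that(length(missing_cl) == 0, sprintf(
    "cell line(s) without expression: %s", paste(missing_cl, collapse = ", ")
  ))

  drug_tab <- dplyr::bind_rows(
    tibble(drug = triplets$drug_a, smiles = triplets$smiles_a),
    tibble(drug = triplets$drug_b, smiles = triplets$smiles_b)
  ) |> distinct(.data$drug, .keep_all = TRUE)
  graphs <- lapply(drug_tab$smiles, smiles_to_graph)
  names(graphs) <- drug_tab$drug
  pre <- lapply(graphs, function(g) list(
    X = g$X,
    Ahat = normalize_adjacency(g$A, cfg$add_self_loops),
    elements = g$elements
  ))
  chem <- NULL
  if (uses_1d(cfg)) {
    chem <- t(vapply(drug_tab$smiles, embed_smiles, numeric(cfg$chem_dim),
      backend = model$backend))
    rownames(chem) <- drug_tab$drug
  }
  list(
    drug_tab = drug_tab, graphs = pre, chem = chem,
    exprz = exprz, genes = model$genes, P = model$P,
    ia = match(triplets$drug_a, drug_tab$drug),
    ib = match(triplets$drug_b, drug_tab$drug),
    ic = match(triplets$cell_line, rownames(exprz)),
    label = if ("label" %in% names(triplets)) as.integer(triplets$label) else
      rep(NA_integer_, nrow(triplets))
  )
}

#' Predict synergy probabilities for triplets
#'
#' Runs the trained network in evaluation mode. With order augmentation
#' (the default), the reported probability is the mean of the forward
#' passes with both drug orders, which makes predictions exactly symmetric
#' in the drug pair.
#'
#' @param object a `drugsyn_model`.
#' @param triplets tibble with `drug_a`, `drug_b`, `smiles_a`, `smiles_b`,
#'   `cell_line` (label optional).
#' @param expression optional expression table for cell lines unseen in
#'   training (same gene panel; z-scored with the training statistics).
#' @param ... unused.
#' @return the input tibble plus `prob_synergy` and `pred` (hard label at
#'   the configured threshold), rows in input order.
#' @export
predict.drugsyn_model <- function(object, triplets, expression = NULL, ...) {
  bundle <- prediction_bundle(object, triplets, expression)
  n <- nrow(triplets)
  rows <- seq_len(n)
  probs <- predict_probs_internal(object, bundle, rows)
  out <- as_tibble(triplets)
  out$prob_synergy <- probs
  out$pred <- as.integer(probs >= object$config$threshold)
  out
}

predict_probs_internal <- function(model, bundle, rows) {
  cfg <- model$config
  batches <- split(rows, ceiling(seq_along(rows) / max(cfg$batch_size, 256)))
  unlist(lapply(batches, function(b) {
    r1 <- model_batch(model$params, bundle, b, cfg, train_mode = FALSE,
      swap = rep(FALSE, length(b)))
    p <- r1$probs[, 2]
    if (cfg$augment && uses_1d(cfg)) {
      r2 <- model_batch(model$params, bundle, b, cfg, train_mode = FALSE,
        swap = rep(TRUE, length(b)))
      p <- (p + r2$probs[, 2]) / 2
    }
    p
  }), use.names = FALSE)
}

#' Screen a drug library against a query drug
#'
#' Enumerates every (library drug, cell line) pairing with the query drug
#' and predicts its synergy probability, the batch-screening mode used to
#' triage candidate partners for a compound of interest.
#'
#' @param model a `drugsyn_model`.
#' @param query_drug,query_smiles identity and SMILES of the query compound.
#' @param library tibble with columns `drug`, `smiles`.
#' @param cell_lines character vector of cell lines (must have expression).
#' @param expression optional expression table (see
#'   [predict.drugsyn_model()]).
#' @return tibble with one row per (library drug, cell line):
#'   `drug_a` (query), `drug_b`, `cell_line`, `prob_synergy`, `pred`.
#' @export
enumerate_screen <- function(model, query_drug, query_smiles, library,
                             cell_lines, expression = NULL) {
  if (nrow(library) == 0 || length(cell_lines) == 0) {
    return(tibble(
      drug_a = character(), drug_b = character(), cell_line = character(),
      prob_synergy = double(), pred = integer()
    ))
  }
  grid <- tidyr::expand_grid(
    drug_b = library$drug,
    cell_line = cell_lines
  ) |>
    left_join(library, by = c(drug_b = "drug")) |>
    mutate(
      drug_a = query_drug, smiles_a = query_smiles,
      smiles_b = .data$smiles
    ) |>
    select("drug_a", "drug_b", "smiles_a", "smiles_b", "cell_line")
  predict(model, grid, expression = expression) |>
    select("drug_a", "drug_b", "cell_line", "prob_synergy", "pred")
}

#' Assemble an untrained model
#'
#' Builds a `drugsyn_model` with freshly initialized weights and no
#' training history, useful for architecture checks, screening-pipeline
#' dry runs, and attention plumbing before any fitting.
#'
#' @inheritParams train_model
#' @return a `drugsyn_model` with untrained parameters.
#' @export
init_model <- function(expression, ppi_embedding, config = model_config(),
                       backend = chem_backend()) {
  exprm <- expression_to_matrix(expression)
  genes <- colnames(exprm)
  assert_that(nrow(ppi_embedding) == length(genes) &&
    all(rownames(ppi_embedding) == genes),
    "ppi_embedding rows must align with the expression gene order")
  zstats <- expression_zscore_stats(exprm)
  structure(
    list(
      params = init_model_params(config, length(genes)),
      config = config,
      backend = backend,
      history = tibble(epoch = integer(), train_loss = double(), val_loss = double()),
      best_epoch = 0L,
      best_val_loss = NA_real_,
      zstats = zstats,
      genes = genes,
      P = unname(ppi_embedding),
      expression = apply_zscore(exprm, zstats),
      cell_lines = rownames(exprm),
      drug_tab = tibble(drug = character(), smiles = character())
    ),
    class = "drugsyn_model"
  )
}
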