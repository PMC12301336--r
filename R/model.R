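# End-to-end model: parameter containers, the batched forward/backward
# engine, and the Adam optimizer. The 2D branch is computed once per unique
# drug (GCN) and unique unordered drug pair (encoder stack) in a batch, and
# the cell-line encoder once per unique cell line; gradients accumulate over
# the rows that share each computation, which is exact because the shared
# computation is a single node in the computation graph.

#' Model configuration
#'
#' Collects every architectural and optimization hyperparameter. Defaults
#' follow the tuned setting: two-layer GCN with widths 78-512-128, two
#' transformer encoder layers with 2 heads of width 32 and a 64-wide
#' feed-forward, 768-d chemical-language drug vectors, a 978-768-512-256
#' cell-line MLP, classifier hidden widths 512-128-32, learning rate 5e-4,
#' dropout 0.3.
#'
#' @param variant `"full"`, `"1d_only"`, `"2d_only"`, or
#'   `"2d_no_graphtrans"` (encoder stack replaced by direct mean pooling).
#' @param gcn_dims GCN layer widths.
#' @param chem_dim chemical-language drug vector width.
#' @param cell_hidden cell-line MLP widths.
#' @param heads,d_k,ffn_dim,n_layers,pool_dim graph-trans pooling shape.
#' @param clf_hidden classifier hidden widths.
#' @param dropout dropout rate (training only).
#' @param lr Adam learning rate.
#' @param batch_size minibatch size.
#' @param epochs maximum training epochs.
#' @param patience early-stopping patience on validation loss.
#' @param val_fraction fraction of training rows held out for validation.
#' @param augment order augmentation: train with random drug-order swaps and
#'   predict as the mean over both drug orders.
#' @param add_self_loops self-loops in adjacency normalization.
#' @param threshold decision threshold on the synergy probability.
#' @param seed integer seed controlling weight init, shuffling and dropout.
#' @return list of class `drugsyn_config`.
#' @export
model_config <- function(variant = c("full", "1d_only", "2d_only", "2d_no_graphtrans"),
                         gcn_dims = c(78, 512, 128), chem_dim = 768,
                         cell_hidden = c(768, 512, 256),
                         heads = 2, d_k = 32, ffn_dim = 64, n_layers = 2,
                         pool_dim = 256, clf_hidden = c(512, 128, 32),
                         dropout = 0.3, lr = 5e-4, batch_size = 128,
                         epochs = 100, patience = 10, val_fraction = 0.1,
                         augment = TRUE, add_self_loops = TRUE,
                         threshold = 0.5, seed = 1) {
  variant <- match.arg(variant)
  structure(
    list(
      variant = variant, gcn_dims = gcn_dims, chem_dim = chem_dim,
      cell_hidden = cell_hidden, model_dim = gcn_dims[3],
      heads = heads, d_k = d_k, ffn_dim = ffn_dim, n_layers = n_layers,
      pool_dim = pool_dim, clf_hidden = clf_hidden, dropout = dropout,
      lr = lr, batch_size = batch_size, epochs = epochs, patience = patience,
      val_fraction = val_fraction, augment = augment,
      add_self_loops = add_self_loops, threshold = threshold, seed = seed
    ),
    class = "drugsyn_config"
  )
}

uses_1d <- function(cfg) cfg$variant %in% c("full", "1d_only")
uses_2d <- function(cfg) cfg$variant %in% c("full", "2d_only", "2d_no_graphtrans")
uses_encoder <- function(cfg) cfg$variant %in% c("full", "2d_only")

clf_input_dim <- function(cfg) {
  w <- 0
  if (uses_1d(cfg)) w <- w + 2 * cfg$chem_dim + cfg$cell_hidden[3]
  if (uses_2d(cfg)) w <- w + cfg$pool_dim
  w
}

#' Initialize all trainable model parameters
#'
#' @param cfg a [model_config()].
#' @param n_genes gene-panel width of the expression input.
#' @param seed integer seed (defaults to the config seed).
#' @return nested parameter list with components for the active branches.
#' @export
init_model_params <- function(cfg, n_genes, seed = cfg$seed) {
  withr_seed(seed, {
    p <- list()
    if (uses_2d(cfg)) {
      p$gcn <- list(
        W0 = glorot(cfg$gcn_dims[1], cfg$gcn_dims[2]),
        W1 = glorot(cfg$gcn_dims[2], cfg$gcn_dims[3])
      )
      if (uses_encoder(cfg)) {
        p$enc <- lapply(seq_len(cfg$n_layers), function(l) {
          init_encoder_params(cfg$model_dim, cfg$heads, cfg$d_k, cfg$ffn_dim)
        })
      }
      p$pool <- list(Wp = glorot(cfg$model_dim, cfg$pool_dim),
                     bp = numeric(cfg$pool_dim))
    }
    if (uses_1d(cfg)) {
      dims <- c(n_genes, cfg$cell_hidden)
      p$cell <- list(
        W = lapply(1:3, function(l) glorot(dims[l], dims[l + 1])),
        b = lapply(1:3, function(l) numeric(dims[l + 1]))
      )
    }
    cw <- c(clf_input_dim(cfg), cfg$clf_hidden, 2)
    p$clf <- list(
      W = lapply(seq_len(length(cw) - 1), function(l) glorot(cw[l], cw[l + 1])),
      b = lapply(seq_len(length(cw) - 1), function(l) numeric(cw[l + 1]))
    )
    p
  })
}

# --- data bundle ----------------------------------------------------------

# Precompute everything that is frozen during training: molecular graphs,
# normalized adjacencies, chemical-language drug vectors, the z-scored
# expression matrix, and the (frozen) PPI embedding.
prepare_model_data <- function(triplets, expression, ppi_embedding, cfg,
                               backend = chem_backend(),
                               zscore_cell_lines = NULL) {
  drug_tab <- dplyr::bind_rows(
    tibble(drug = triplets$drug_a, smiles = triplets$smiles_a),
    tibble(drug = triplets$drug_b, smiles = triplets$smiles_b)
  ) |> distinct(.data$drug, .keep_all = TRUE)

  graphs <- NULL
  parse_errors <- character(0)
  graphs <- lapply(seq_len(nrow(drug_tab)), function(i) {
    tryCatch(smiles_to_graph(drug_tab$smiles[i]), error = function(e) {
      parse_errors <<- c(parse_errors, drug_tab$drug[i])
      NULL
    })
  })
  if (length(parse_errors) > 0) {
    abort(sprintf(
      "SMILES failed to parse for drug(s): %s", paste(parse_errors, collapse = ", ")
    ))
  }
  names(graphs) <- drug_tab$drug

  expr <- expression_to_matrix(expression)
  missing_cl <- setdiff(unique(triplets$cell_line), rownames(expr))
  if (length(missing_cl) > 0) {
    abort(sprintf(
      "cell line(s) absent from the expression matrix: %s",
      paste(missing_cl, collapse = ", ")
    ))
  }
  genes <- colnames(expr)
  assert_that(nrow(ppi_embedding) == length(genes) &&
    all(rownames(ppi_embedding) == genes),
    "ppi_embedding rows must align with the expression gene order; see align_embedding()")
  assert_that(ncol(ppi_embedding) == cfg$model_dim, sprintf(
    "ppi embedding width %d must equal model_dim %d", ncol(ppi_embedding), cfg$model_dim
  ))

  zstats <- expression_zscore_stats(expr, zscore_cell_lines)
  exprz <- apply_zscore(expr, zstats)

  chem <- NULL
  if (uses_1d(cfg)) {
    chem <- t(vapply(drug_tab$smiles, embed_smiles, numeric(cfg$chem_dim),
      backend = backend))
    rownames(chem) <- drug_tab$drug
  }
  pre <- lapply(graphs, function(g) {
    list(
      X = g$X,
      Ahat = normalize_adjacency(g$A, cfg$add_self_loops),
      elements = g$elements
    )
  })

  list(
    drug_tab = drug_tab, graphs = pre, chem = chem,
    exprz = exprz, zstats = zstats, genes = genes,
    P = unname(ppi_embedding),
    ia = match(triplets$drug_a, drug_tab$drug),
    ib = match(triplets$drug_b, drug_tab$drug),
    ic = match(triplets$cell_line, rownames(expr)),
    label = if ("label" %in% names(triplets)) as.integer(triplets$label) else
      rep(NA_integer_, nrow(triplets))
  )
}

# --- forward/backward over one batch --------------------------------------

# rows: indices into bundle triplets; swap: logical per row (drug order for
# the 1D block); returns loss/probs and, if need_grads, accumulated grads.
model_batch <- function(params, bundle, rows, cfg, train_mode = FALSE,
                        swap = NULL, need_grads = FALSE, collect = FALSE) {
  B <- length(rows)
  if (is.null(swap)) swap <- rep(FALSE, B)
  ia <- bundle$ia[rows]; ib <- bundle$ib[rows]; ic <- bundle$ic[rows]
  drop_rate <- if (train_mode) cfg$dropout else 0

  # ---- GCN over unique drugs, stacked so the weight matmuls run once per
  # batch over all atoms instead of once per small molecule
  drug_cache <- NULL
  gcn_stack <- NULL
  if (uses_2d(cfg)) {
    uds <- sort(unique(c(ia, ib)))
    nv <- vapply(uds, function(d) nrow(bundle$graphs[[d]]$X), integer(1))
    ends <- cumsum(nv)
    starts <- ends - nv + 1L
    Xall <- do.call(rbind, lapply(uds, function(d) bundle$graphs[[d]]$X))
    XW <- Xall %*% params$gcn$W0
    U0s <- vector("list", length(uds))
    H1s <- vector("list", length(uds))
    for (j in seq_along(uds)) {
      U0s[[j]] <- bundle$graphs[[uds[j]]]$Ahat %*%
        XW[starts[j]:ends[j], , drop = FALSE]
      H1s[[j]] <- relu(U0s[[j]])
    }
    H1all <- do.call(rbind, H1s)
    M1 <- H1all %*% params$gcn$W1
    drug_cache <- lapply(seq_along(uds), function(j) {
      U1 <- bundle$graphs[[uds[j]]]$Ahat %*%
        M1[starts[j]:ends[j], , drop = FALSE]
      list(d = uds[j], j = j, H2 = relu(U1), U1 = U1, U0 = U0s[[j]])
    })
    names(drug_cache) <- as.character(uds)
    gcn_stack <- list(Xall = Xall, H1all = H1all, starts = starts, ends = ends)
  }

  # ---- encoder stack over unique (unordered) pairs
  pair_cache <- NULL
  feat2d <- NULL
  pair_of_row <- NULL
  if (uses_2d(cfg)) {
    p1 <- pmin(ia, ib); p2 <- pmax(ia, ib)
    pk <- paste(p1, p2)
    upairs <- !duplicated(pk)
    pair_ids <- pk[upairs]
    pair_cache <- vector("list", length(pair_ids))
    names(pair_cache) <- pair_ids
    for (j in seq_along(pair_ids)) {
      da <- p1[upairs][j]; db <- p2[upairs][j]
      Ha <- drug_cache[[as.character(da)]]$H2
      Hb <- drug_cache[[as.character(db)]]$H2
      X <- rbind(Ha, Hb, bundle$P)
      if (uses_encoder(cfg)) {
        # fused C++ stack: encoder layers + mean pool + ReLU projection,
        # with all intermediates cached behind an external pointer
        fwd <- graph_stack_fwd_cpp(X, params$enc, params$pool$Wp,
          params$pool$bp, drop_rate, train_mode, collect)
        records <- NULL
        if (collect) {
          roles <- tibble(
            role = rep(c("atomA", "atomB", "gene"),
              c(nrow(Ha), nrow(Hb), nrow(bundle$P))),
            label = c(
              paste0(bundle$graphs[[da]]$elements, ":", seq_len(nrow(Ha))),
              paste0(bundle$graphs[[db]]$elements, ":", seq_len(nrow(Hb))),
              bundle$genes
            ),
            index = c(seq_len(nrow(Ha)), seq_len(nrow(Hb)),
              seq_len(nrow(bundle$P)))
          )
          records <- list()
          for (l in seq_len(cfg$n_layers)) {
            for (i in seq_len(cfg$heads)) {
              records[[length(records) + 1]] <- new_attention_record(
                layer = l, head = i,
                scores = fwd$scores[[(l - 1) * cfg$heads + i]],
                roles = roles
              )
            }
          }
        }
        pair_cache[[j]] <- list(
          da = da, db = db, va = nrow(Ha), vb = nrow(Hb),
          cptr = fwd$cache, feat = as.numeric(fwd$feature),
          records = records
        )
      } else {
        m <- colMeans(X)
        z <- as.numeric(m %*% params$pool$Wp) + params$pool$bp
        pair_cache[[j]] <- list(
          da = da, db = db, va = nrow(Ha), vb = nrow(Hb),
          Z = X, m = m, z = z, feat = relu(z), records = NULL
        )
      }
    }
    pair_of_row <- match(pk, pair_ids)
    feat2d <- do.call(rbind, lapply(pair_cache, function(pc) pc$feat))
  }

  # ---- cell-line encoder over unique cell lines
  cell_cache <- NULL
  cellvec <- NULL
  cell_of_row <- NULL
  if (uses_1d(cfg)) {
    ucells <- sort(unique(ic))
    cell_cache <- lapply(ucells, function(cl) {
      x <- matrix(bundle$exprz[cl, ], nrow = 1)
      Z1 <- x %*% params$cell$W[[1]] + matrix(params$cell$b[[1]], 1)
      H1 <- relu(Z1)
      m1 <- if (train_mode) dropout_mask(1, ncol(H1), drop_rate) else NULL
      D1 <- apply_mask(H1, m1)
      Z2 <- D1 %*% params$cell$W[[2]] + matrix(params$cell$b[[2]], 1)
      H2 <- relu(Z2)
      m2 <- if (train_mode) dropout_mask(1, ncol(H2), drop_rate) else NULL
      D2 <- apply_mask(H2, m2)
      Z3 <- D2 %*% params$cell$W[[3]] + matrix(params$cell$b[[3]], 1)
      list(cl = cl, x = x, Z1 = Z1, D1 = D1, m1 = m1,
           Z2 = Z2, D2 = D2, m2 = m2, out = Z3)
    })
    names(cell_cache) <- as.character(ucells)
    cell_of_row <- match(ic, ucells)
    cellvec <- do.call(rbind, lapply(cell_cache, function(cc) cc$out))
  }

  # ---- classifier; its first layer is evaluated per unique entity
  # The fused feature concatenates block-shared vectors (drug embeddings,
  # cell encodings, pair features), so X W1 is computed once per unique
  # drug/cell/pair and gathered per row -- exact, and much cheaper than
  # materializing the dense B x input feature matrix.
  nh <- length(cfg$clf_hidden)
  W1 <- params$clf$W[[1]]
  blk <- list()
  if (uses_1d(cfg)) {
    first <- ifelse(swap, ib, ia)
    second <- ifelse(swap, ia, ib)
    blk$chemA <- list(U = bundle$chem, idx = first, frozen = TRUE)
    blk$chemB <- list(U = bundle$chem, idx = second, frozen = TRUE)
    blk$cell <- list(U = cellvec, idx = cell_of_row, frozen = FALSE)
  }
  if (uses_2d(cfg)) {
    blk$f2d <- list(U = feat2d, idx = pair_of_row, frozen = FALSE)
  }
  off <- 0
  for (k in seq_along(blk)) {
    w <- ncol(blk[[k]]$U)
    blk[[k]]$cols <- (off + 1):(off + w)
    off <- off + w
  }
  Z1 <- matrix(params$clf$b[[1]], B, ncol(W1), byrow = TRUE)
  for (bk in blk) {
    Z1 <- Z1 + (bk$U %*% W1[bk$cols, , drop = FALSE])[bk$idx, , drop = FALSE]
  }
  H1 <- relu(Z1)
  mk1 <- if (train_mode) dropout_mask(B, ncol(H1), drop_rate) else NULL
  A <- apply_mask(H1, mk1)
  clf_cache <- vector("list", nh)
  clf_cache[[1]] <- list(Z = Z1, mask = mk1)
  if (nh >= 2) {
    for (l in 2:nh) {
      Z <- bias_add(A %*% params$clf$W[[l]], params$clf$b[[l]])
      H <- relu(Z)
      mk <- if (train_mode) dropout_mask(nrow(H), ncol(H), drop_rate) else NULL
      D <- apply_mask(H, mk)
      clf_cache[[l]] <- list(A_in = A, Z = Z, mask = mk)
      A <- D
    }
  }
  logits <- bias_add(A %*% params$clf$W[[nh + 1]], params$clf$b[[nh + 1]])
  probs <- softmax_rows(logits)

  y <- bundle$label[rows]
  loss <- NA_real_
  if (!anyNA(y)) {
    p_true <- pmax(probs[cbind(seq_len(B), y + 1L)], 1e-12)
    loss <- -mean(log(p_true))
  }

  out <- list(
    loss = loss, probs = probs, logits = logits,
    hidden = if (collect) list(
      h512 = relu(Z1),
      h32 = clf_cache_last_hidden(clf_cache, params, nh)
    ) else NULL,
    records = if (collect && uses_2d(cfg) && uses_encoder(cfg)) {
      unlist(lapply(pair_cache, function(pc) pc$records), recursive = FALSE)
    } else NULL
  )
  if (!need_grads) return(out)

  # ---- backward
  Y <- matrix(0, B, 2)
  Y[cbind(seq_len(B), y + 1L)] <- 1
  dlogits <- (probs - Y) / B

  grads <- list()
  grads$clf <- list(W = vector("list", nh + 1), b = vector("list", nh + 1))
  grads$clf$W[[nh + 1]] <- crossprod(A, dlogits)
  grads$clf$b[[nh + 1]] <- colSums(dlogits)
  dA <- tcrossprod(dlogits, params$clf$W[[nh + 1]])
  if (nh >= 2) {
    for (l in rev(2:nh)) {
      cc <- clf_cache[[l]]
      dD <- apply_mask(dA, cc$mask)
      dZ <- dD * (cc$Z > 0)
      grads$clf$W[[l]] <- crossprod(cc$A_in, dZ)
      grads$clf$b[[l]] <- colSums(dZ)
      dA <- tcrossprod(dZ, params$clf$W[[l]])
    }
  }
  # first layer: accumulate per block over unique entities
  dZ1 <- apply_mask(dA, clf_cache[[1]]$mask) * (Z1 > 0)
  grads$clf$b[[1]] <- colSums(dZ1)
  gW1 <- W1 * 0
  dU <- list()
  for (k in seq_along(blk)) {
    bk <- blk[[k]]
    S <- group_sum_rows(dZ1, bk$idx, nrow(bk$U))
    gW1[bk$cols, ] <- gW1[bk$cols, ] + crossprod(bk$U, S)
    if (!bk$frozen) {
      dU[[names(blk)[k]]] <- tcrossprod(S, W1[bk$cols, , drop = FALSE])
    }
  }
  grads$clf$W[[1]] <- gW1

  if (uses_1d(cfg)) {
    dcell_u <- dU$cell
    grads$cell <- list(
      W = lapply(params$cell$W, function(w) w * 0),
      b = lapply(params$cell$b, function(b) b * 0)
    )
    for (j in seq_along(cell_cache)) {
      cc <- cell_cache[[j]]
      dout <- matrix(dcell_u[j, ], 1)
      grads$cell$W[[3]] <- grads$cell$W[[3]] + crossprod(cc$D2, dout)
      grads$cell$b[[3]] <- grads$cell$b[[3]] + as.numeric(dout)
      dD2 <- tcrossprod(dout, params$cell$W[[3]])
      dH2 <- apply_mask(dD2, cc$m2) * (cc$Z2 > 0)
      grads$cell$W[[2]] <- grads$cell$W[[2]] + crossprod(cc$D1, dH2)
      grads$cell$b[[2]] <- grads$cell$b[[2]] + as.numeric(dH2)
      dD1 <- tcrossprod(dH2, params$cell$W[[2]])
      dH1 <- apply_mask(dD1, cc$m1) * (cc$Z1 > 0)
      grads$cell$W[[1]] <- grads$cell$W[[1]] + crossprod(cc$x, dH1)
      grads$cell$b[[1]] <- grads$cell$b[[1]] + as.numeric(dH1)
    }
  }

  if (uses_2d(cfg)) {
    dfeat_u <- dU$f2d
    grads$pool <- list(Wp = params$pool$Wp * 0, bp = params$pool$bp * 0)
    if (uses_encoder(cfg)) grads$enc <- lapply(params$enc, zero_like)
    grads$gcn <- list(W0 = params$gcn$W0 * 0, W1 = params$gcn$W1 * 0)
    dH_drug <- lapply(drug_cache, function(dc) dc$H2 * 0)

    for (j in seq_along(pair_cache)) {
      pc <- pair_cache[[j]]
      dfeat <- dfeat_u[j, ]
      if (uses_encoder(cfg)) {
        bw <- graph_stack_bwd_cpp(dfeat, pc$cptr, params$enc, params$pool$Wp)
        for (l in seq_len(cfg$n_layers)) {
          grads$enc[[l]] <- acc_grads(grads$enc[[l]], bw$enc[[l]])
        }
        grads$pool$Wp <- grads$pool$Wp + bw$pool$Wp
        grads$pool$bp <- grads$pool$bp + as.numeric(bw$pool$bp)
        dX <- bw$dX
      } else {
        dz <- dfeat * (pc$z > 0)
        grads$pool$Wp <- grads$pool$Wp + outer(pc$m, dz)
        grads$pool$bp <- grads$pool$bp + dz
        dm <- as.numeric(params$pool$Wp %*% dz)
        T_ <- nrow(pc$Z)
        dX <- matrix(rep(dm / T_, each = T_), T_, length(dm))
      }
      ka <- as.character(pc$da); kb <- as.character(pc$db)
      dH_drug[[ka]] <- dH_drug[[ka]] + dX[seq_len(pc$va), , drop = FALSE]
      dH_drug[[kb]] <- dH_drug[[kb]] +
        dX[(pc$va + 1):(pc$va + pc$vb), , drop = FALSE]
      # gene token gradient discarded: PPI embeddings are frozen
    }

    # stacked GCN backward (Ahat is symmetric, so Ahat^T = Ahat)
    dM1all <- matrix(0, nrow(gcn_stack$H1all), ncol(params$gcn$W1))
    for (k in names(drug_cache)) {
      dc <- drug_cache[[k]]
      rng <- gcn_stack$starts[dc$j]:gcn_stack$ends[dc$j]
      dU1 <- dH_drug[[k]] * (dc$U1 > 0)
      dM1all[rng, ] <- bundle$graphs[[dc$d]]$Ahat %*% dU1
    }
    grads$gcn$W1 <- crossprod(gcn_stack$H1all, dM1all)
    dH1all <- tcrossprod(dM1all, params$gcn$W1)
    dXWall <- matrix(0, nrow(gcn_stack$Xall), ncol(params$gcn$W0))
    for (k in names(drug_cache)) {
      dc <- drug_cache[[k]]
      rng <- gcn_stack$starts[dc$j]:gcn_stack$ends[dc$j]
      dU0 <- dH1all[rng, , drop = FALSE] * (dc$U0 > 0)
      dXWall[rng, ] <- bundle$graphs[[dc$d]]$Ahat %*% dU0
    }
    grads$gcn$W0 <- crossprod(gcn_stack$Xall, dXWall)
  }

  out$grads <- grads
  out
}

# recompute the 32-wide hidden layer (third hidden) in eval mode from cache
clf_cache_last_hidden <- function(clf_cache, params, nh) {
  relu(clf_cache[[nh]]$Z)
}

# --- Adam -----------------------------------------------------------------

adam_init <- function(params) {
  list(m = zero_like(params), v = zero_like(params), t = 0)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  upd <- function(p, g, m, v) {
    if (is.list(p)) {
      out_p <- p; out_m <- m; out_v <- v
      nm <- names(p)
      for (k in seq_along(p)) {
        gk <- if (!is.null(nm) && nzchar(nm[k]) && !is.null(g[[nm[k]]])) {
          g[[nm[k]]]
        } else {
          g[[k]]
        }
        r <- upd(p[[k]], gk, m[[k]], v[[k]])
        out_p[[k]] <- r$p; out_m[[k]] <- r$m; out_v[[k]] <- r$v
      }
      list(p = out_p, m = out_m, v = out_v)
    } else {
      m <- beta1 * m + (1 - beta1) * g
      v <- beta2 * v + (1 - beta2) * g^2
      p <- p - lr * (m / bc1) / (sqrt(v / bc2) + eps)
      list(p = p, m = m, v = v)
    }
  }
  r <- upd(params, grads, state$m, state$v)
  list(params = r$p, state = list(m = r$m, v = r$v, t = state$t))
}
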