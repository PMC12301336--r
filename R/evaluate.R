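# The eight-metric evaluation panel and cross-validation driver.

#' Compute the eight-metric evaluation panel
#'
#' Threshold-free ranking metrics: AUROC by the rank (Mann-Whitney)
#' statistic with ties contributing 1/2, and AUPR by step-wise
#' precision-recall integration (average precision). Thresholded metrics
#' from the confusion matrix at `threshold`: accuracy, balanced accuracy
#' `(TPR + TNR) / 2`, precision, TPR (recall), F1, and Cohen's kappa
#' `(p_o - p_e) / (1 - p_e)`. If the truth contains a single class, the
#' ranking metrics are reported as `NA` with `rank_metrics_defined = FALSE`
#' rather than silently zero.
#'
#' @param truth integer vector of 0/1 labels.
#' @param probs predicted synergy probabilities, same length.
#' @param threshold decision threshold (default 0.5; predictions use
#'   `probs >= threshold`).
#' @return one-row tibble: `auroc`, `aupr`, `acc`, `bacc`, `prec`, `tpr`,
#'   `kappa`, `f1`, `n_test`, `threshold`, `rank_metrics_defined`.
#' @export
#' @examples
#' compute_metrics(c(1, 1, 1, 0, 0, 0), c(1, 1, 0, 1, 0, 0))
compute_metrics <- function(truth, probs, threshold = 0.5) {
  assert_that(length(truth) == length(probs), "truth and probs length mismatch")
  truth <- as.integer(truth)
  assert_that(all(truth %in% c(0L, 1L)), "truth must be 0/1")
  n <- length(truth)
  n_pos <- sum(truth == 1L)
  n_neg <- n - n_pos
  two_class <- n_pos > 0 && n_neg > 0

  auroc <- aupr <- NA_real_
  if (two_class) {
    r <- rank(probs) # midranks handle ties as 1/2
    auroc <- (sum(r[truth == 1L]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
    aupr <- average_precision(truth, probs)
  }

  pred <- as.integer(probs >= threshold)
  tp <- sum(pred == 1L & truth == 1L)
  fp <- sum(pred == 1L & truth == 0L)
  fn <- sum(pred == 0L & truth == 1L)
  tn <- sum(pred == 0L & truth == 0L)
  acc <- (tp + tn) / n
  tpr <- if (n_pos > 0) tp / n_pos else NA_real_
  tnr <- if (n_neg > 0) tn / n_neg else NA_real_
  bacc <- mean(c(tpr, tnr), na.rm = TRUE)
  prec <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  f1 <- if (is.na(prec) || is.na(tpr) || prec + tpr == 0) NA_real_ else
    2 * prec * tpr / (prec + tpr)
  p_o <- acc
  p_e <- ((tp + fp) * n_pos + (tn + fn) * n_neg) / n^2
  kappa <- if (p_e < 1) (p_o - p_e) / (1 - p_e) else NA_real_

  tibble(
    auroc = auroc, aupr = aupr, acc = acc, bacc = bacc, prec = prec,
    tpr = tpr, kappa = kappa, f1 = f1,
    n_test = n, threshold = threshold, rank_metrics_defined = two_class
  )
}

# Average precision: sum over descending-score steps of precision * delta
# recall, with tied scores collapsed into a single step.
average_precision <- function(truth, probs) {
  ord <- order(probs, decreasing = TRUE)
  t_sorted <- truth[ord]
  p_sorted <- probs[ord]
  tp_cum <- cumsum(t_sorted == 1L)
  n_cum <- seq_along(t_sorted)
  # indices ending each tie group
  last_of_group <- which(p_sorted != c(p_sorted[-1], NA))
  last_of_group[length(last_of_group) + 1] <- length(p_sorted)
  last_of_group <- unique(last_of_group)
  n_pos <- sum(truth == 1L)
  prev_recall <- 0
  ap <- 0
  for (i in last_of_group) {
    precision <- tp_cum[i] / n_cum[i]
    recall <- tp_cum[i] / n_pos
    ap <- ap + precision * (recall - prev_recall)
    prev_recall <- recall
  }
  ap
}

#' Cross-validate a model configuration over a split plan
#'
#' Retrains the model from scratch on every fold's training rows and
#' evaluates the eight-metric panel on the fold's test rows. For
#' leave-group-out plans the group-exclusion property is re-asserted inside
#' the loop before any training happens.
#'
#' @param triplets labeled triplet tibble.
#' @param expression expression table or matrix.
#' @param ppi_embedding aligned node-embedding matrix.
#' @param plan a `drugsyn_split`.
#' @param config a [model_config()].
#' @param backend a [chem_backend()].
#' @param quiet suppress per-epoch training messages (default TRUE).
#' @return A `drugsyn_cv`: list with `folds` (tibble, one metric row per
#'   fold), `summary` (mean and sample standard deviation per metric),
#'   `scheme`, and `config`.
#' @export
run_cross_validation <- function(triplets, expression, ppi_embedding, plan,
                                 config = model_config(),
                                 backend = chem_backend(), quiet = TRUE) {
  n <- nrow(triplets)
  for (f in plan$folds) {
    assert_that(all(c(f$train, f$test) >= 1) && all(c(f$train, f$test) <= n),
      "split plan indices outside the dataset")
    assert_that(length(intersect(f$train, f$test)) == 0,
      "split plan has overlapping train/test indices")
  }
  assert_group_exclusion(triplets, plan)

  fold_rows <- vector("list", length(plan$folds))
  for (i in seq_along(plan$folds)) {
    f <- plan$folds[[i]]
    fit <- tryCatch(
      train_model(triplets[f$train, ], expression, ppi_embedding,
        config = config, backend = backend, quiet = quiet),
      error = function(e) abort(sprintf("training failed in fold %d: %s",
        i, conditionMessage(e)))
    )
    pred <- predict(fit, triplets[f$test, ])
    m <- compute_metrics(triplets$label[f$test], pred$prob_synergy,
      threshold = config$threshold)
    fold_rows[[i]] <- mutate(m, fold = i, .before = 1)
  }
  folds <- dplyr::bind_rows(fold_rows)
  metric_cols <- c("auroc", "aupr", "acc", "bacc", "prec", "tpr", "kappa", "f1")
  summary <- tidyr::pivot_longer(folds[, metric_cols], dplyr::everything(),
    names_to = "metric", values_to = "value") |>
    group_by(.data$metric) |>
    summarise(
      mean = mean(.data$value, na.rm = TRUE),
      sd = sd(.data$value, na.rm = TRUE),
      .groups = "drop"
    ) |>
    mutate(metric = factor(.data$metric, levels = metric_cols)) |>
    arrange(.data$metric) |>
    mutate(metric = as.character(.data$metric))
  structure(
    list(folds = folds, summary = summary, scheme = plan$scheme,
      config = config),
    class = "drugsyn_cv"
  )
}

# Re-verify the defining property of group-out plans by exhaustive scan.
assert_group_exclusion <- function(triplets, plan) {
  if (!grepl("^leave_", plan$scheme) || is.null(plan$groups)) return(invisible())
  kind <- sub("^leave_", "", plan$scheme)
  for (i in seq_along(plan$folds)) {
    f <- plan$folds[[i]]
    gs <- plan$groups[[i]]
    in_group <- function(rows) {
      if (kind == "drug") {
        triplets$drug_a[rows] %in% gs | triplets$drug_b[rows] %in% gs
      } else if (kind == "combination") {
        keys <- vapply(strsplit(gs, "|", fixed = TRUE),
          function(p) pair_key(p[1], p[2]), character(1))
        pair_key(triplets$drug_a[rows], triplets$drug_b[rows]) %in% keys
      } else if (kind == "cell_line") {
        triplets$cell_line[rows] %in% gs
      } else {
        rep(FALSE, length(rows)) # tissue membership checked at plan build
      }
    }
    assert_that(!any(in_group(f$train)), sprintf(
      "fold %d training set contains held-out group member(s)", i
    ))
  }
  invisible()
}

#' @export
print.drugsyn_cv <- function(x, ...) {
  cat(sprintf("<drugsyn_cv> scheme=%s, %d folds, variant=%s\n",
    x$scheme, nrow(x$folds), x$config$variant))
  s <- x$summary
  cat(paste(sprintf("  %-5s %.3f +/- %.3f", s$metric, s$mean, s$sd),
    collapse = "\n"), "\n")
  invisible(x)
}

#' @describeIn run_cross_validation per-fold metric rows.
#' @param x a `drugsyn_cv`.
#' @param ... unused.
#' @method tidy drugsyn_cv
#' @export
tidy.drugsyn_cv <- function(x, ...) x$folds

#' @describeIn run_cross_validation metric means and standard deviations as
#'   one wide row.
#' @method glance drugsyn_cv
#' @export
glance.drugsyn_cv <- function(x, ...) {
  wide <- setNames(as.list(x$summary$mean), x$summary$metric)
  dplyr::bind_cols(
    tibble(scheme = x$scheme, variant = x$config$variant,
      n_folds = nrow(x$folds)),
    as_tibble(wide)
  )
}

#' @describeIn run_cross_validation per-fold metric dot plot.
#' @param object a `drugsyn_cv`.
#' @method autoplot drugsyn_cv
#' @export
autoplot.drugsyn_cv <- function(object, ...) {
  metric_cols <- c("auroc", "aupr", "acc", "bacc", "prec", "tpr", "kappa", "f1")
  df <- tidyr::pivot_longer(object$folds[, c("fold", metric_cols)],
    -"fold", names_to = "metric", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$metric, y = .data$value)) +
    ggplot2::geom_point(ggplot2::aes(colour = factor(.data$fold)), alpha = 0.8) +
    ggplot2::stat_summary(fun = mean, geom = "crossbar", width = 0.4,
      linewidth = 0.3) +
    ggplot2::labs(x = NULL, y = "metric value", colour = "fold") +
    ggplot2::theme_minimal()
}

#' Write cross-validation reports to disk
#'
#' @param cv a `drugsyn_cv`.
#' @param json_path,tsv_path output paths (either may be `NULL`).
#' @export
write_cv_report <- function(cv, json_path = NULL, tsv_path = NULL) {
  if (!is.null(json_path)) {
    jsonlite::write_json(
      list(scheme = cv$scheme, folds = cv$folds, summary = cv$summary),
      json_path, dataframe = "rows", auto_unbox = TRUE, digits = NA
    )
  }
  if (!is.null(tsv_path)) {
    readr::write_tsv(cv$folds, tsv_path)
  }
  invisible(cv)
}
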