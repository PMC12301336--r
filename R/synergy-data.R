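#' Read a drug-combination synergy table
#'
#' Reads a comma- or tab-separated text file of drug pair--cell line records
#' with Loewe synergy scores. The file must carry a header naming the five
#' required columns (`drug_a`, `drug_b`, `smiles_a`, `smiles_b`, `cell_line`,
#' `score`); column order is irrelevant because parsing is header-keyed.
#' Rows whose score cannot be parsed as a number are dropped with a warning
#' reporting how many were skipped.
#'
#' @param path path to a delimited text file.
#' @return A tibble with columns `drug_a`, `drug_b`, `smiles_a`, `smiles_b`,
#'   `cell_line` (character) and `score` (double), one row per usable record.
#' @export
#' @examples
#' tf <- tempfile(fileext = ".csv")
#' writeLines(c("drug_a,drug_b,smiles_a,smiles_b,cell_line,score",
#'              "A,B,C,CC,cl1,12.5"), tf)
#' load_combination_table(tf)
load_combination_table <- function(path) {
  required <- c("drug_a", "drug_b", "smiles_a", "smiles_b", "cell_line", "score")
  raw <- readr::read_delim(
    path,
    delim = guess_delim(path),
    col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE
  )
  missing <- setdiff(required, names(raw))
  if (length(missing) > 0) {
    abort(sprintf(
      "combination table %s is missing required column(s): %s",
      path, paste(missing, collapse = ", ")
    ))
  }
  if (nrow(raw) == 0) {
    warn(sprintf("combination table %s has a header but no rows", path))
    return(tibble(
      drug_a = character(), drug_b = character(),
      smiles_a = character(), smiles_b = character(),
      cell_line = character(), score = double()
    ))
  }
  out <- raw |>
    select(dplyr::all_of(required)) |>
    mutate(score = suppressWarnings(as.numeric(.data$score)))
  n_bad <- sum(is.na(out$score))
  if (n_bad > 0) {
    warn(sprintf("skipped %d row(s) with unparseable synergy scores", n_bad))
    out <- filter(out, !is.na(.data$score))
  }
  bad_smiles <- out$smiles_a == "" | out$smiles_b == ""
  if (any(bad_smiles)) {
    warn(sprintf("skipped %d row(s) with empty SMILES", sum(bad_smiles)))
    out <- out[!bad_smiles, ]
  }
  out
}

guess_delim <- function(path) {
  first <- readLines(path, n = 1L)
  if (grepl("\t", first, fixed = TRUE)) "\t" else ","
}

#' Average duplicated drug pair--cell line records
#'
#' Records sharing the same unordered drug pair and cell line are collapsed
#' to a single record whose score is the arithmetic mean of the duplicates.
#' The surviving record keeps the drug order and SMILES of the first
#' occurrence.
#'
#' @param records tibble of synergy records as returned by
#'   [load_combination_table()].
#' @return tibble with one row per unordered (drug pair, cell line) key.
#' @export
average_duplicates <- function(records) {
  if (nrow(records) == 0) return(records)
  records |>
    mutate(.key = pair_key(.data$drug_a, .data$drug_b), .cl = .data$cell_line) |>
    group_by(.data$.key, .data$.cl) |>
    summarise(
      drug_a = .data$drug_a[1], drug_b = .data$drug_b[1],
      smiles_a = .data$smiles_a[1], smiles_b = .data$smiles_b[1],
      cell_line = .data$cell_line[1],
      score = mean(.data$score),
      .groups = "drop"
    ) |>
    select(-".key", -".cl")
}

#' Label triplets by synergy-score thresholds
#'
#' Scores strictly above `pos_thr` become synergistic (label 1); scores
#' strictly below `neg_thr` become antagonistic (label 0). Scores falling in
#' the closed interval `[neg_thr, pos_thr]` are ambiguous under the Loewe
#' additivity reading and are dropped, with the drop count reported.
#'
#' @param records tibble of (deduplicated) synergy records.
#' @param pos_thr positive threshold; default 10.
#' @param neg_thr negative threshold; default 0.
#' @param quiet suppress the drop-count message.
#' @return tibble of labeled triplets: identity columns plus integer `label`.
#' @export
label_by_threshold <- function(records, pos_thr = 10, neg_thr = 0, quiet = FALSE) {
  assert_that(neg_thr <= pos_thr, "neg_thr must not exceed pos_thr")
  lab <- ifelse(records$score > pos_thr, 1L,
    ifelse(records$score < neg_thr, 0L, NA_integer_)
  )
  n_drop <- sum(is.na(lab))
  if (!quiet && nrow(records) > 0) {
    inform(sprintf(
      "labelled %d triplets (%d synergistic, %d antagonistic); dropped %d with scores in [%g, %g]",
      sum(!is.na(lab)), sum(lab == 1L, na.rm = TRUE), sum(lab == 0L, na.rm = TRUE),
      n_drop, neg_thr, pos_thr
    ))
  }
  out <- records
  out$label <- lab
  out <- filter(out, !is.na(.data$label))
  attr(out, "n_dropped") <- n_drop
  out
}

#' Read a cell-line expression matrix
#'
#' Tab-separated text; first column `cell_line`, remaining columns named by
#' gene symbol. The landmark-gene panel has 978 genes, but the count is not
#' enforced here so that reduced synthetic panels load identically.
#'
#' @param path path to the TSV file.
#' @return tibble with `cell_line` plus one numeric column per gene.
#' @export
load_expression_matrix <- function(path) {
  out <- readr::read_tsv(path, col_types = readr::cols(
    cell_line = readr::col_character(), .default = readr::col_double()
  ), progress = FALSE)
  assert_that("cell_line" %in% names(out), "expression matrix needs a cell_line column")
  genes <- setdiff(names(out), "cell_line")
  assert_that(!anyDuplicated(genes), "duplicate gene columns in expression matrix")
  out
}

# Expression tibble -> numeric matrix with cell-line rownames.
expression_to_matrix <- function(expression) {
  if (is.matrix(expression)) return(expression)
  m <- as.matrix(expression[, setdiff(names(expression), "cell_line")])
  rownames(m) <- expression$cell_line
  m
}

#' Build a random k-fold cross-validation plan
#'
#' Indices are shuffled reproducibly and dealt into `k` folds whose sizes
#' differ by at most one; each fold's test set is one part and its training
#' set is the rest.
#'
#' @param triplets tibble of labeled triplets (only the row count is used).
#' @param k number of folds (default 5).
#' @param seed integer seed controlling the shuffle.
#' @return A `drugsyn_split` object: list with `scheme` and `folds`, each
#'   fold holding integer `train` and `test` index vectors.
#' @export
make_random_kfold <- function(triplets, k = 5, seed = 1) {
  n <- nrow(triplets)
  assert_that(k >= 2, "k must be at least 2")
  assert_that(n >= k, sprintf("cannot split %d triplets into %d folds", n, k))
  idx <- withr_seed(seed, sample.int(n))
  fold_of <- rep(seq_len(k), length.out = n)
  folds <- lapply(seq_len(k), function(f) {
    test <- sort(idx[fold_of == f])
    list(train = setdiff(seq_len(n), test), test = test)
  })
  new_split_plan("random_kfold", folds)
}

# Evaluate expr under a local RNG seed without disturbing the global stream.
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

new_split_plan <- function(scheme, folds, groups = NULL) {
  structure(
    list(scheme = scheme, folds = folds, groups = groups),
    class = "drugsyn_split"
  )
}

#' @export
print.drugsyn_split <- function(x, ...) {
  cat(sprintf(
    "<drugsyn_split> scheme=%s, %d fold(s); test sizes: %s\n",
    x$scheme, length(x$folds),
    paste(vapply(x$folds, function(f) length(f$test), integer(1)), collapse = ", ")
  ))
  invisible(x)
}

#' @method tidy drugsyn_split
#' @export
tidy.drugsyn_split <- function(x, ...) {
  purrr::map_dfr(seq_along(x$folds), function(i) {
    tibble(
      fold = i,
      n_train = length(x$folds[[i]]$train),
      n_test = length(x$folds[[i]]$test),
      held_out = if (is.null(x$groups)) NA_character_ else
        paste(x$groups[[i]], collapse = ";")
    )
  })
}

# Grouping key of each triplet for a given scheme.
triplet_group <- function(triplets, group_by, tissue_map = NULL) {
  switch(group_by,
    combination = pair_key(triplets$drug_a, triplets$drug_b),
    drug = NULL, # drugs need set membership, handled separately
    cell_line = triplets$cell_line,
    tissue = {
      assert_that(!is.null(tissue_map), "tissue scheme needs a tissue_map")
      tm <- setNames(tissue_map$tissue, tissue_map$cell_line)
      missing <- setdiff(unique(triplets$cell_line), names(tm))
      assert_that(length(missing) == 0, sprintf(
        "tissue_map does not cover cell line(s): %s", paste(missing, collapse = ", ")
      ))
      unname(tm[triplets$cell_line])
    },
    abort(sprintf("unknown group_by '%s'", group_by))
  )
}

#' Build a leave-group-out cross-validation plan
#'
#' One fold per element of `groups` (or per subset when `groups` is a list):
#' the test set is exactly the triplets whose group matches the held-out
#' group(s), and those triplets never appear in training. Grouping units are
#' unordered drug combinations, single drugs (a triplet matches if either
#' member is the held-out drug), cell lines, or tissues via an explicit
#' cell-line-to-tissue map.
#'
#' @param triplets tibble of labeled triplets.
#' @param group_by one of `"combination"`, `"drug"`, `"cell_line"`, `"tissue"`.
#' @param groups character vector (one group per fold) or list of character
#'   vectors (one subset of groups per fold). For `"combination"`, each group
#'   is `"drugX|drugY"` (order irrelevant).
#' @param tissue_map tibble with columns `cell_line`, `tissue`; required for
#'   the tissue scheme.
#' @return a `drugsyn_split` object.
#' @export
make_leave_group_out <- function(triplets, group_by, groups, tissue_map = NULL) {
  assert_that(length(groups) > 0, "groups must be non-empty")
  if (!is.list(groups)) groups <- as.list(groups)
  n <- nrow(triplets)
  match_rows <- function(gs) {
    if (group_by == "drug") {
      which(triplets$drug_a %in% gs | triplets$drug_b %in% gs)
    } else if (group_by == "combination") {
      keys <- vapply(strsplit(gs, "|", fixed = TRUE), function(p) {
        assert_that(length(p) == 2, "combination groups must be 'drugA|drugB'")
        pair_key(p[1], p[2])
      }, character(1))
      which(pair_key(triplets$drug_a, triplets$drug_b) %in% keys)
    } else {
      which(triplet_group(triplets, group_by, tissue_map) %in% gs)
    }
  }
  folds <- lapply(groups, function(gs) {
    test <- match_rows(gs)
    assert_that(length(test) > 0, sprintf(
      "no triplet matches held-out group(s): %s", paste(gs, collapse = ", ")
    ))
    list(train = setdiff(seq_len(n), test), test = test)
  })
  new_split_plan(paste0("leave_", group_by), folds, groups = groups)
}

#' Rank grouping units by triplet frequency
#'
#' Counts how many triplets each group covers and returns the groups in
#' descending frequency order, with lexicographic tie-breaking so that the
#' ranking is reproducible.
#'
#' @inheritParams make_leave_group_out
#' @return tibble with columns `group` and `n`, most frequent first.
#' @export
rank_groups_by_frequency <- function(triplets, group_by, tissue_map = NULL) {
  if (nrow(triplets) == 0) {
    return(tibble(group = character(), n = integer()))
  }
  g <- if (group_by == "drug") {
    c(triplets$drug_a, triplets$drug_b)
  } else if (group_by == "combination") {
    paste(
      pmin(triplets$drug_a, triplets$drug_b),
      pmax(triplets$drug_a, triplets$drug_b),
      sep = "|"
    )
  } else {
    triplet_group(triplets, group_by, tissue_map)
  }
  tab <- table(g)
  tibble(group = names(tab), n = as.integer(tab)) |>
    arrange(desc(.data$n), .data$group)
}

#' Serialize a split plan to JSON
#'
#' @param plan a `drugsyn_split` object.
#' @param path output path.
#' @export
write_split_plan <- function(plan, path) {
  jsonlite::write_json(
    list(
      scheme = plan$scheme,
      folds = lapply(plan$folds, function(f) list(train = f$train, test = f$test))
    ),
    path,
    auto_unbox = TRUE
  )
  invisible(path)
}

#' @rdname write_split_plan
#' @export
read_split_plan <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  folds <- lapply(seq_len(nrow_folds(x$folds)), function(i) {
    list(
      train = as.integer(x$folds$train[[i]]),
      test = as.integer(x$folds$test[[i]])
    )
  })
  new_split_plan(x$scheme, folds)
}

nrow_folds <- function(folds) {
  if (is.data.frame(folds)) nrow(folds) else length(folds)
}
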