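# Softmax MLP classifier over the fused multidimensional feature.

#' Initialize classifier parameters
#'
#' Dense chain with hidden widths 512, 128, 32 and a 2-class output layer;
#' the default input width 2048 is the concatenation of the 1792-d 1D
#' feature and the 256-d 2D feature.
#'
#' @param input_dim fused feature width (default 2048).
#' @param hidden hidden widths (default `c(512, 128, 32)`).
#' @param dropout dropout rate in training mode.
#' @param seed integer seed.
#' @return list of class `drugsyn_classifier`.
#' @export
init_classifier <- function(input_dim = 2048, hidden = c(512, 128, 32),
                            dropout = 0.3, seed = 1) {
  dims <- c(input_dim, hidden, 2)
  withr_seed(seed, structure(
    list(
      W = lapply(seq_len(length(dims) - 1), function(l) glorot(dims[l], dims[l + 1])),
      b = lapply(seq_len(length(dims) - 1), function(l) numeric(dims[l + 1])),
      dropout = dropout
    ),
    class = "drugsyn_classifier"
  ))
}

#' Classifier forward pass
#'
#' Concatenates the 1D and 2D features and applies the ReLU hidden chain
#' followed by the linear output layer:
#' \eqn{a^{(l)} = \mathrm{ReLU}(W_l a^{(l-1)} + b_l)},
#' \eqn{y' = W_{out} a^{(L)} + b_{out}}.
#'
#' @param feature_1d,feature_2d numeric feature vectors (either may be
#'   `NULL` for ablation variants, as long as the concatenation matches the
#'   classifier input width).
#' @param params a `drugsyn_classifier`.
#' @param train_mode logical; dropout active only when `TRUE`.
#' @return list with `logits` (length 2) and `hidden`, the list of hidden
#'   activations (so the 512- and 32-wide layers are retrievable for
#'   embedding projections).
#' @export
classifier_forward <- function(feature_1d, feature_2d, params,
                               train_mode = FALSE) {
  a <- c(feature_1d, feature_2d)
  assert_that(length(a) == nrow(params$W[[1]]), sprintf(
    "fused feature width %d does not match classifier input %d",
    length(a), nrow(params$W[[1]])
  ))
  A <- matrix(a, nrow = 1)
  nh <- length(params$W) - 1
  hidden <- vector("list", nh)
  for (l in seq_len(nh)) {
    A <- relu(sweep(A %*% params$W[[l]], 2, params$b[[l]], "+"))
    hidden[[l]] <- as.numeric(A)
    if (train_mode && params$dropout > 0) {
      A <- apply_mask(A, dropout_mask(1, ncol(A), params$dropout))
    }
  }
  logits <- as.numeric(A %*% params$W[[nh + 1]] + matrix(params$b[[nh + 1]], 1))
  list(logits = logits, hidden = hidden)
}

#' Softmax class probabilities from logits
#'
#' Log-sum-exp stabilized, so very large logits do not overflow.
#'
#' @param logits numeric vector (one example) or matrix (rows = examples).
#' @return probabilities of the same shape; rows are positive and sum to 1.
#' @export
#' @examples
#' predict_proba(c(0, 0))
#' predict_proba(c(log(3), 0))
predict_proba <- function(logits) {
  check_finite(logits, "logits")
  p <- softmax_rows(logits)
  if (is.null(dim(logits))) as.numeric(p) else p
}

#' Mean cross-entropy loss
#'
#' \eqn{L = -\frac{1}{N}\sum_i \log p_i(y_i)} where \eqn{p_i(y_i)} is the
#' predicted probability of example *i*'s true class. Probabilities are
#' floored at 1e-12 before the logarithm.
#'
#' @param probs numeric matrix of class probabilities (rows = examples,
#'   columns = classes) or a vector for a single example.
#' @param labels integer class labels in `0..K-1`.
#' @return non-negative scalar loss (mean over examples).
#' @export
cross_entropy <- function(probs, labels) {
  if (is.null(dim(probs))) probs <- matrix(probs, nrow = 1)
  assert_that(nrow(probs) == length(labels), "probs and labels length mismatch")
  p_true <- probs[cbind(seq_len(nrow(probs)), as.integer(labels) + 1L)]
  -mean(log(pmax(p_true, 1e-12)))
}
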