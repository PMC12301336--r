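# Internal numerical and bookkeeping helpers shared across modules.

relu <- function(x) {
  x[x < 0] <- 0
  x
}

#' Row-wise softmax with log-sum-exp stabilisation
#'
#' @param x numeric matrix (or vector, treated as one row).
#' @return matrix of the same shape whose rows are probability vectors.
#' @keywords internal
#' @noRd
softmax_rows <- function(x) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  m <- x[cbind(seq_len(nrow(x)), max.col(x, ties.method = "first"))]
  e <- exp(x - m)
  e / rowSums(e)
}

# Fast row-broadcast helpers (avoid sweep's generality in hot paths).
bias_add <- function(X, b) X + rep(b, each = nrow(X))
col_scale <- function(X, s) X * rep(s, each = nrow(X))

# One-hot with a terminal "other" bucket: values outside `levels` (or beyond
# the last bucket for integer ranges) map to the final slot.
one_hot_bucket <- function(value, levels) {
  v <- numeric(length(levels))
  i <- match(value, levels)
  if (is.na(i)) i <- length(levels)
  v[i] <- 1
  v
}

# Deterministic 31-bit polynomial hash of an integer vector; platform
# independent (pure double arithmetic below 2^53).
hash_ints <- function(xs, seed = 17) {
  h <- seed
  for (x in xs) {
    h <- (h * 33 + (x %% 2147483629) + 1) %% 2147483629
  }
  h
}

# Stable key for an unordered drug pair.
pair_key <- function(a, b) {
  ifelse(a <= b, paste(a, b, sep = "\r"), paste(b, a, sep = "\r"))
}

assert_that <- function(ok, msg) {
  if (!ok) abort(msg)
  invisible(TRUE)
}

check_finite <- function(x, what) {
  if (!all(is.finite(x))) {
    abort(sprintf("non-finite values encountered in %s", what))
  }
  invisible(TRUE)
}

# Sum the rows of M by group index (1..n), returning an n x ncol(M) matrix
# with zero rows for absent groups.
group_sum_rows <- function(M, idx, n) {
  rs <- rowsum(M, idx)
  out <- matrix(0, n, ncol(M))
  out[as.integer(rownames(rs)), ] <- rs
  out
}
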