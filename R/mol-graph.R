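# SMILES -> molecular graph featurization and the two-layer GCN encoder.

# 44-symbol element vocabulary (final slot is the "other" bucket), following
# the featurization lineage shared by molecular-graph synergy models.
ATOM_SYMBOLS <- c(
  "C", "N", "O", "S", "F", "Si", "P", "Cl", "Br", "Mg", "Na", "Ca", "Fe",
  "As", "Al", "I", "B", "V", "K", "Tl", "Yb", "Sb", "Sn", "Ag", "Pd", "Co",
  "Se", "Ti", "Zn", "H", "Li", "Ge", "Cu", "Au", "Ni", "Cd", "In", "Mn",
  "Zr", "Cr", "Pt", "Hg", "Pb", "other"
)

# Default valences used only for the bondless fallback below.
DEFAULT_VALENCE <- c(
  C = 4, N = 3, O = 2, S = 2, F = 1, Cl = 1, Br = 1, I = 1, P = 3, B = 3,
  Si = 4, Se = 2, As = 3, H = 1
)

#' Convert a SMILES string to a molecular graph
#'
#' Parses the SMILES with OpenBabel (via ChemmineOB/ChemmineR) into a
#' heavy-atom graph: one node per non-hydrogen atom, one undirected edge per
#' bond, a binary symmetric adjacency matrix with zero diagonal, and a
#' 78-dimensional feature row per atom built by [atom_features()].
#' Aromaticity comes from ring perception of the parsed structure.
#' Multi-fragment SMILES (salts) are kept whole as a disconnected graph.
#'
#' @param smiles a single SMILES string.
#' @return A `drugsyn_molgraph`: list with `X` (V x 78 feature matrix), `A`
#'   (V x V binary adjacency), `elements` (atom symbols), `aromatic`
#'   (logical per atom), and the source `smiles`.
#' @export
#' @examples
#' g <- smiles_to_graph("c1ccccc1")
#' g$A
smiles_to_graph <- function(smiles) {
  assert_that(is.character(smiles) && length(smiles) == 1 && nzchar(smiles),
    "smiles must be a single non-empty string")
  parsed <- parse_smiles(smiles)
  V <- length(parsed$elements)
  feats <- lapply(seq_len(V), function(i) {
    atom_features(
      element = parsed$elements[i],
      degree = parsed$degree[i],
      n_h = parsed$n_h[i],
      implicit_valence = parsed$implicit_valence[i],
      aromatic = parsed$aromatic[i]
    )
  })
  structure(
    list(
      X = do.call(rbind, feats),
      A = parsed$A,
      elements = parsed$elements,
      aromatic = parsed$aromatic,
      smiles = smiles
    ),
    class = "drugsyn_molgraph"
  )
}

#' @export
print.drugsyn_molgraph <- function(x, ...) {
  cat(sprintf(
    "<drugsyn_molgraph> %s: %d atoms, %d bonds, %d aromatic atoms\n",
    x$smiles, nrow(x$A), sum(x$A) / 2, sum(x$aromatic)
  ))
  invisible(x)
}

# Parse one SMILES into elements / adjacency / descriptors. OpenBabel does
# the chemistry (via ChemmineOB); ChemmineR supplies the bond table, valence
# rules, and aromatic-ring perception. Zero-bond molecules (single heavy
# atoms, bare ions) are read from the V2000 atom lines directly because the
# SDF reader rejects structures without a bond block.
parse_smiles <- function(smiles) {
  sdf_txt <- tryCatch(
    ChemmineOB::convertFormat("SMI", "SDF", paste0(smiles, "\tmol\n")),
    error = function(e) ""
  )
  if (!nzchar(sdf_txt) || !grepl("V2000", sdf_txt, fixed = TRUE)) {
    abort(sprintf("SMILES string could not be parsed: '%s'", smiles))
  }
  lines <- strsplit(sdf_txt, "\n", fixed = TRUE)[[1]]
  counts_i <- grep("V2000", lines, fixed = TRUE)[1]
  n_atoms <- as.integer(substr(lines[counts_i], 1, 3))
  n_bonds <- as.integer(substr(lines[counts_i], 4, 6))
  if (is.na(n_atoms) || n_atoms < 1) {
    abort(sprintf("SMILES string could not be parsed: '%s'", smiles))
  }
  if (is.na(n_bonds) || n_bonds == 0) {
    return(parse_bondless_sdf(lines, counts_i, n_atoms))
  }

  sdf <- suppressWarnings(ChemmineR::read.SDFset(lines))[[1]]
  orders <- ChemmineR::conMA(sdf)
  bt <- ChemmineR::bonds(sdf, type = "bonds")
  elements <- as.character(bt$atom)
  charges <- as.integer(bt$charge)
  A <- (orders > 0) * 1
  diag(A) <- 0

  aromatic <- aromatic_atoms(sdf, n_atoms)

  # drop explicit hydrogens, remembering how many were attached to each atom
  is_h <- elements == "H"
  explicit_h <- as.integer(A %*% as.numeric(is_h))
  keep <- which(!is_h)
  assert_that(length(keep) >= 1, sprintf("SMILES '%s' has no heavy atoms", smiles))
  # ChemmineR's valence rule is charge-adjusted for cations only; subtract
  # the magnitude of negative charges (e.g. carboxylate O-) ourselves
  implicit_h <- pmax(0L, as.integer(bt$Nbondrule) - as.integer(bt$Nbondcount) +
    pmin(charges, 0L))
  A <- A[keep, keep, drop = FALSE]
  list(
    elements = elements[keep],
    A = unname(A),
    aromatic = aromatic[keep],
    degree = as.integer(rowSums(A)),
    n_h = implicit_h[keep] + explicit_h[keep],
    implicit_valence = implicit_h[keep]
  )
}

# Atoms belonging to at least one aromatic ring, per ChemmineR perception.
aromatic_atoms <- function(sdf, n_atoms) {
  aromatic <- rep(FALSE, n_atoms)
  rng <- tryCatch(
    ChemmineR::rings(sdf, type = "all", arom = TRUE),
    error = function(e) NULL
  )
  if (!is.null(rng) && length(rng$RINGS) > 0) {
    for (k in seq_along(rng$RINGS)) {
      if (isTRUE(rng$AROMATIC[[k]])) {
        idx <- as.integer(sub(".*_", "", rng$RINGS[[k]]))
        aromatic[idx] <- TRUE
      }
    }
  }
  aromatic
}

parse_bondless_sdf <- function(lines, counts_i, n_atoms) {
  atom_lines <- lines[(counts_i + 1):(counts_i + n_atoms)]
  elements <- stringr::str_trim(substr(atom_lines, 32, 34))
  charges <- integer(n_atoms)
  for (cl in grep("^M  CHG", lines, value = TRUE)) {
    nums <- as.integer(strsplit(stringr::str_squish(substr(cl, 7, nchar(cl))), " ")[[1]])
    for (e in seq_len(nums[1])) charges[nums[2 * e]] <- nums[2 * e + 1]
  }
  keep <- which(elements != "H")
  assert_that(length(keep) >= 1, "molecule has no heavy atoms")
  elements <- elements[keep]
  charges <- charges[keep]
  val <- unname(DEFAULT_VALENCE[elements])
  val[is.na(val)] <- 0
  h <- pmax(0L, as.integer(val) + ifelse(charges > 0 & elements %in% c("N", "P"),
    charges, -abs(charges)))
  V <- length(keep)
  list(
    elements = elements,
    A = matrix(0, V, V),
    aromatic = rep(FALSE, V),
    degree = rep(0L, V),
    n_h = h,
    implicit_valence = h
  )
}

#' Build the 78-dimensional atom feature vector
#'
#' Concatenates: element one-hot over a 44-symbol vocabulary with an "other"
#' bucket; degree one-hot over 0..10; attached-hydrogen one-hot over 0..10;
#' implicit-valence one-hot over 0..10; and a single aromaticity flag.
#' Out-of-range counts fall into the final bucket of their block.
#'
#' @param element atom symbol, e.g. `"C"`.
#' @param degree number of heavy-atom neighbours.
#' @param n_h attached hydrogen count (implicit + explicit).
#' @param implicit_valence implicit hydrogen count.
#' @param aromatic logical aromaticity flag.
#' @return numeric vector of length 78 with entries in `{0, 1}`.
#' @export
atom_features <- function(element, degree, n_h, implicit_valence, aromatic) {
  c(
    one_hot_bucket(element, ATOM_SYMBOLS),
    one_hot_bucket(min(degree, 10), 0:10),
    one_hot_bucket(min(n_h, 10), 0:10),
    one_hot_bucket(min(implicit_valence, 10), 0:10),
    as.numeric(isTRUE(aromatic))
  )
}

#' Symmetrically normalize an adjacency matrix
#'
#' Computes the renormalized propagation matrix of graph convolution:
#' with self-loops, \eqn{\hat A = \tilde D^{-1/2} (A + I) \tilde D^{-1/2}};
#' without, \eqn{D^{-1/2} A D^{-1/2}} with zero-degree rows left at zero.
#'
#' @param A square symmetric binary adjacency matrix.
#' @param add_self_loops add the identity before normalizing (default TRUE).
#' @return normalized adjacency of the same dimension.
#' @export
normalize_adjacency <- function(A, add_self_loops = TRUE) {
  assert_that(is.matrix(A) && nrow(A) == ncol(A), "A must be a square matrix")
  assert_that(isTRUE(all.equal(unname(A), unname(t(A)))), "A must be symmetric")
  if (add_self_loops) A <- A + diag(nrow(A))
  d <- rowSums(A)
  inv_sqrt <- ifelse(d > 0, 1 / sqrt(d), 0)
  A * outer(inv_sqrt, inv_sqrt)
}

#' Initialize GCN weights
#'
#' @param dims integer vector of layer widths, default `c(78, 512, 128)`.
#' @param seed integer seed.
#' @return list with weight matrices `W0` and `W1`.
#' @export
init_gcn_params <- function(dims = c(78, 512, 128), seed = 1) {
  assert_that(length(dims) == 3, "two-layer GCN needs three widths")
  withr_seed(seed, list(
    W0 = glorot(dims[1], dims[2]),
    W1 = glorot(dims[2], dims[3])
  ))
}

glorot <- function(n_in, n_out) {
  s <- sqrt(6 / (n_in + n_out))
  matrix(runif(n_in * n_out, -s, s), n_in, n_out)
}

#' Two-layer graph convolution forward pass
#'
#' Runs \eqn{h^{(1)} = \mathrm{ReLU}(\hat A X W^{(0)})} and
#' \eqn{h^{(2)} = \mathrm{ReLU}(\hat A h^{(1)} W^{(1)})} over the molecular
#' graph, producing one embedding row per atom.
#'
#' @param graph a `drugsyn_molgraph`.
#' @param params GCN parameters from [init_gcn_params()].
#' @param add_self_loops passed to [normalize_adjacency()].
#' @return V x d node-embedding matrix (non-negative).
#' @export
gcn_forward <- function(graph, params, add_self_loops = TRUE) {
  assert_that(ncol(graph$X) == nrow(params$W0), sprintf(
    "feature width %d does not match W0 rows %d", ncol(graph$X), nrow(params$W0)
  ))
  A_hat <- normalize_adjacency(graph$A, add_self_loops)
  h1 <- relu(A_hat %*% (graph$X %*% params$W0))
  relu(A_hat %*% (h1 %*% params$W1))
}
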