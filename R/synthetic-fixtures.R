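# Offline synthetic data with the statistical structure the model assumes:
# valid drug-like molecules, a scale-free PPI graph, Gaussian expression
# with a planted signature, and triplet labels from a stated rule with flip
# noise. Fixtures emit exactly the file formats the real pipeline consumes.

# Curated drug-like SMILES: roughly half contain an aromatic ring and half
# are purely aliphatic, which the planted rule below relies on.
SMILES_LIBRARY <- c(
  # aromatic scaffolds
  "CC(=O)Oc1ccccc1C(=O)O",                   # aspirin
  "CC(=O)Nc1ccc(O)cc1",                      # paracetamol
  "CC(C)Cc1ccc(cc1)C(C)C(=O)O",              # ibuprofen
  "Cn1cnc2c1c(=O)n(C)c(=O)n2C",              # caffeine
  "CCOC(=O)c1ccc(N)cc1",                     # benzocaine
  "OC(=O)c1ccccc1O",                         # salicylic acid
  "NC(=O)c1cccnc1",                          # nicotinamide
  "NNC(=O)c1ccncc1",                         # isoniazid
  "NC(=O)c1cnccn1",                          # pyrazinamide
  "Oc1cccc(O)c1",                            # resorcinol
  "COc1ccc2cc(ccc2c1)C(C)C(=O)O",            # naproxen
  "CN1C(=O)CN=C(c2ccccc2)c2cc(Cl)ccc21",     # diazepam
  "Fc1c[nH]c(=O)[nH]c1=O",                   # 5-fluorouracil
  "O=C1NC(=O)C(c2ccccc2)(c2ccccc2)N1",       # phenytoin
  "CCN(CC)CCOC(=O)c1ccc(N)cc1",              # procaine
  "CCN(CC)CC(=O)Nc1c(C)cccc1C",              # lidocaine
  "Nc1ccc(cc1)S(N)(=O)=O",                   # sulfanilamide
  "COc1cc(Cc2cnc(N)nc2N)cc(OC)c1OC",         # trimethoprim
  "CN1CCCC1c1cccnc1",                        # nicotine
  "CC(=O)NCCc1c[nH]c2ccc(OC)cc12",           # melatonin
  "NCCc1ccc(O)c(O)c1",                       # dopamine
  "CC(C)NCC(O)COc1cccc2ccccc12",             # propranolol
  "CC(C)NCC(O)COc1ccc(CC(N)=O)cc1",          # atenolol
  "Cc1ncc(n1CCO)[N+](=O)[O-]",               # metronidazole
  "O=C1NC=NC2=C1C=NN2",                      # allopurinol
  "Cn1c(=O)c2[nH]cnc2n(C)c1=O",              # theophylline
  "CNCC(O)c1cccc(O)c1",                      # phenylephrine
  "NCCc1ccc(O)cc1",                          # tyramine
  "Oc1cccc2cccnc12",                         # 8-hydroxyquinoline
  "OC(=O)Cc1ccccc1",                         # phenylacetic acid
  # aliphatic scaffolds
  "CN(C)C(=N)NC(=N)N",                       # metformin
  "CCCC(CCC)C(=O)O",                         # valproic acid
  "NCC1(CC(=O)O)CCCCC1",                     # gabapentin
  "C1C2CC3CC1CC(C2)(C3)N",                   # amantadine
  "CC12CC3CC(C)(C1)CC(N)(C3)C2",             # memantine
  "CC(C)CC(CN)CC(=O)O",                      # pregabalin
  "C=CC(N)CCC(=O)O",                         # vigabatrin
  "NCCCCCC(=O)O",                            # aminocaproic acid
  "CCCC(C)(COC(N)=O)COC(=O)NC(C)C",          # carisoprodol
  "OC(O)C(Cl)(Cl)Cl",                        # chloral hydrate
  "NC(=N)NCCCC(N)C(=O)O",                    # arginine
  "CC(C)CC(N)C(=O)O",                        # leucine
  "NCCCCC(N)C(=O)O",                         # lysine
  "OC(=O)CC(O)(C(=O)O)CC(=O)O",              # citric acid
  "OC(=O)CCC(=O)O",                          # succinic acid
  "OCC1OC(O)C(O)C(O)C1O",                    # glucose
  "OCC(O)C(O)C(O)C(O)CO",                    # mannitol
  "OCCCC(=O)O",                              # gamma-hydroxybutyrate
  "CC(C)(CO)C(O)C(=O)NCCC(=O)O",             # pantothenic acid
  "NCC1CCC(CC1)C(=O)O",                      # tranexamic acid
  "NC1CONC1=O",                              # cycloserine
  "CCC1(C)CC(=O)NC1=O",                      # ethosuximide
  "CC1(C)C2CCC(C)(O2)CC1",                   # eucalyptol
  "CC(C)C1CCC(C)CC1O",                       # menthol
  "CC1(C)C2CCC1(C)C(=O)C2",                  # camphor
  "COC(=O)C=CC(=O)OC",                       # dimethyl fumarate
  "CC(=O)NC(CS)C(=O)O",                      # acetylcysteine
  "NCCS(=O)(=O)O",                           # taurine
  "OC1COC2C1OCC2O",                          # isosorbide
  "NCCCCNCCCN"                               # spermidine
)

#' Configuration for the synthetic study
#'
#' Defaults define the desk-scale study conditions: 20 drugs, 15 cell
#' lines, a 60-gene panel, 2,000 triplets, and 10% label-flip noise.
#'
#' @param n_drugs drugs drawn from the in-package SMILES library.
#' @param n_cell_lines synthetic cell lines.
#' @param n_genes gene-panel width (use 978 for full-shape runs).
#' @param n_triplets labeled triplets to sample.
#' @param noise label-flip probability, in `[0, 0.5)`.
#' @param attachment edges added per node in the scale-free PPI generator.
#' @param n_signature_genes genes carrying the expression signature shift.
#' @param seed integer seed.
#' @return list of class `drugsyn_fixture_config`.
#' @export
fixture_config <- function(n_drugs = 20, n_cell_lines = 15, n_genes = 60,
                           n_triplets = 2000, noise = 0.1, attachment = 2,
                           n_signature_genes = 10, seed = 1) {
  assert_that(noise >= 0 && noise < 0.5, "noise must be in [0, 0.5)")
  assert_that(n_drugs > 0 && n_cell_lines > 0 && n_genes >= 3 && n_triplets > 0,
    "counts must be positive (n_genes >= 3)")
  structure(
    list(
      n_drugs = n_drugs, n_cell_lines = n_cell_lines, n_genes = n_genes,
      n_triplets = n_triplets, noise = noise, attachment = attachment,
      n_signature_genes = min(n_signature_genes, n_genes), seed = seed
    ),
    class = "drugsyn_fixture_config"
  )
}

#' Draw a drug library of valid SMILES
#'
#' Samples without replacement from the curated in-package library of
#' drug-like SMILES (aromatic and aliphatic scaffolds); every entry parses
#' with [smiles_to_graph()].
#'
#' @param n_drugs library size, at most `length(drugsyn:::SMILES_LIBRARY)`.
#' @param seed integer seed.
#' @return tibble with `drug` (ids `D01`, `D02`, ...), `smiles`, and
#'   `aromatic` (whether the molecule contains an aromatic ring).
#' @export
make_smiles_library <- function(n_drugs, seed = 1) {
  assert_that(n_drugs <= length(SMILES_LIBRARY), sprintf(
    "n_drugs must be at most the library capacity (%d)", length(SMILES_LIBRARY)
  ))
  smiles <- withr_seed(seed, sample(SMILES_LIBRARY, n_drugs))
  aromatic <- vapply(smiles, function(s) any(smiles_to_graph(s)$aromatic),
    logical(1))
  tibble(
    drug = sprintf("D%02d", seq_len(n_drugs)),
    smiles = smiles,
    aromatic = unname(aromatic)
  )
}

#' Generate a scale-free synthetic PPI network
#'
#' Preferential attachment: starting from `m` seed nodes, each subsequent
#' node attaches to `m` distinct existing nodes with probability
#' proportional to degree + 1, giving exactly `(n - m) * m` edges and a
#' connected, right-skewed degree distribution.
#'
#' @param n_genes number of nodes (gene symbols `G0001`, ...).
#' @param attachment `m`, edges per incoming node (default 2).
#' @param seed integer seed.
#' @return a `drugsyn_ppi`.
#' @export
make_synthetic_ppi <- function(n_genes, attachment = 2, seed = 1) {
  assert_that(n_genes >= 3, "n_genes must be at least 3")
  m <- attachment
  assert_that(m >= 1 && m < n_genes, "attachment must be in [1, n_genes)")
  genes <- sprintf("G%04d", seq_len(n_genes))
  edges <- withr_seed(seed, {
    deg <- numeric(n_genes)
    from <- integer(0); to <- integer(0)
    for (v in (m + 1):n_genes) {
      existing <- seq_len(v - 1)
      w <- deg[existing] + 1
      targets <- sample(existing, min(m, length(existing)), prob = w)
      from <- c(from, rep(v, length(targets)))
      to <- c(to, targets)
      deg[targets] <- deg[targets] + 1
      deg[v] <- deg[v] + length(targets)
    }
    cbind(from, to)
  })
  ppi_network(genes[edges[, 1]], genes[edges[, 2]], nodes = genes)
}

#' Generate synthetic cell-line expression with a planted signature
#'
#' Standard-normal expression for every gene, plus a +2 shift on the
#' signature gene set (first `n_signature_genes` genes) for a randomly
#' chosen half of the cell lines. The shifted cell lines are the
#' "signature" cell lines the planted label rule refers to.
#'
#' @param cell_lines character vector of cell-line ids.
#' @param n_genes gene-panel width.
#' @param n_signature_genes size of the shifted gene set (default 10).
#' @param shift signature shift size (default 2).
#' @param seed integer seed.
#' @return tibble (`cell_line` + gene columns) with attributes
#'   `signature_genes` and `signature_cell_lines`.
#' @export
make_synthetic_expression <- function(cell_lines, n_genes,
                                      n_signature_genes = 10, shift = 2,
                                      seed = 1) {
  n_cl <- length(cell_lines)
  genes <- sprintf("G%04d", seq_len(n_genes))
  sig_genes <- genes[seq_len(min(n_signature_genes, n_genes))]
  out <- withr_seed(seed, {
    m <- matrix(rnorm(n_cl * n_genes), n_cl, n_genes,
      dimnames = list(cell_lines, genes))
    sig_cl <- sort(sample(cell_lines, floor(n_cl / 2)))
    m[sig_cl, sig_genes] <- m[sig_cl, sig_genes] + shift
    list(m = m, sig_cl = sig_cl)
  })
  df <- as_tibble(out$m, rownames = "cell_line")
  attr(df, "signature_genes") <- sig_genes
  attr(df, "signature_cell_lines") <- out$sig_cl
  df
}

#' Sample labeled triplets from the planted rule
#'
#' The noiseless rule is `label = [both drugs aromatic] XOR [cell line
#' carries the signature shift]`, so neither the drug-structure modality
#' nor the expression modality alone determines the label. The sampler
#' draws triplets stratified by rule outcome to keep the class balance
#' within 40-60%, then flips each label independently with probability
#' `noise`. Synthetic Loewe-style scores consistent with the noisy labels
#' are attached so fixtures can exercise the thresholding pipeline.
#'
#' @param smiles_lib tibble from [make_smiles_library()].
#' @param expression tibble from [make_synthetic_expression()].
#' @param config a [fixture_config()].
#' @return list with `triplets` (tibble: identity columns, `score`,
#'   `label`) and `rule` (tibble: `true_label`, `flipped`), plus the rule
#'   description string.
#' @export
make_labeled_triplets <- function(smiles_lib, expression, config) {
  sig_cl <- attr(expression, "signature_cell_lines")
  assert_that(!is.null(sig_cl), "expression lacks the signature attribute")
  cells <- expression$cell_line
  nd <- nrow(smiles_lib)
  pairs <- which(upper.tri(matrix(0, nd, nd)), arr.ind = TRUE)
  grid <- tidyr::expand_grid(pair = seq_len(nrow(pairs)), cell = cells)
  i <- pairs[grid$pair, 1]
  j <- pairs[grid$pair, 2]
  both_arom <- smiles_lib$aromatic[i] & smiles_lib$aromatic[j]
  in_sig <- grid$cell %in% sig_cl
  rule <- as.integer(xor(both_arom, in_sig))

  withr_seed(config$seed + 7L, {
    n <- config$n_triplets
    n1 <- round(n / 2)
    pool1 <- which(rule == 1L)
    pool0 <- which(rule == 0L)
    take1 <- min(n1, length(pool1))
    take0 <- min(n - take1, length(pool0))
    assert_that(take1 + take0 == n, sprintf(
      "fixture capacity %d is below n_triplets %d", length(rule), n
    ))
    sel <- c(sample(pool1, take1), sample(pool0, take0))
    sel <- sel[sample.int(length(sel))]

    true_label <- rule[sel]
    flipped <- runif(n) < config$noise
    label <- ifelse(flipped, 1L - true_label, true_label)
    score <- ifelse(label == 1L, 10 + 0.5 + abs(rnorm(n, sd = 8)),
      -(0.5 + abs(rnorm(n, sd = 8))))
    triplets <- tibble(
      drug_a = smiles_lib$drug[i[sel]],
      drug_b = smiles_lib$drug[j[sel]],
      smiles_a = smiles_lib$smiles[i[sel]],
      smiles_b = smiles_lib$smiles[j[sel]],
      cell_line = grid$cell[sel],
      score = score,
      label = label
    )
    bal <- mean(label)
    assert_that(bal >= 0.35 && bal <= 0.65, sprintf(
      "sampler produced class balance %.2f outside 40-60%% band", bal
    ))
    list(
      triplets = triplets,
      rule = tibble(true_label = true_label, flipped = flipped),
      rule_description = "both-drugs-aromatic XOR signature-cell-line"
    )
  })
}

#' Highest AUROC attainable under the flip-noise model
#'
#' With flip probability `noise` and a deterministic binary rule, the
#' Bayes-optimal scorer attains AUROC `1 - noise` against the noisy labels
#' (correct-pair probability `(1-noise)^2` plus half the tie mass).
#'
#' @param noise flip probability.
#' @return the AUROC ceiling.
#' @export
planted_rule_ceiling <- function(noise) 1 - noise

#' Generate the complete synthetic study
#'
#' One call producing every input the pipeline consumes: drug library,
#' scale-free PPI network over the synthetic gene panel, expression with a
#' planted signature, labeled triplets from the planted rule, and a
#' round-robin tissue map for leave-tissue-out splits.
#'
#' @param config a [fixture_config()].
#' @return list with `smiles_lib`, `ppi`, `expression`, `triplets`, `rule`,
#'   `tissue_map`, and `config`.
#' @export
make_fixture_dataset <- function(config = fixture_config()) {
  smiles_lib <- make_smiles_library(config$n_drugs, seed = config$seed)
  ppi <- make_synthetic_ppi(config$n_genes, config$attachment,
    seed = config$seed + 1L)
  cells <- sprintf("CL%02d", seq_len(config$n_cell_lines))
  expression <- make_synthetic_expression(cells, config$n_genes,
    n_signature_genes = config$n_signature_genes, seed = config$seed + 2L)
  lab <- make_labeled_triplets(smiles_lib, expression, config)
  tissues <- c("lung", "skin", "intestine", "ovary", "breast")
  tissue_map <- tibble(
    cell_line = cells,
    tissue = rep(tissues, length.out = length(cells))
  )
  list(
    smiles_lib = smiles_lib, ppi = ppi, expression = expression,
    triplets = lab$triplets, rule = lab$rule,
    rule_description = lab$rule_description,
    tissue_map = tissue_map, config = config
  )
}

#' Write a synthetic study to the on-disk formats the pipeline reads
#'
#' Emits `combinations.csv` (drug pair--cell line scores), `expression.tsv`,
#' `ppi_edges.tsv`, and `tissue_map.tsv` under `dir`.
#'
#' @param fixture list from [make_fixture_dataset()].
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_fixture_files <- function(fixture, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(
    fixture$triplets[, c("drug_a", "drug_b", "smiles_a", "smiles_b",
      "cell_line", "score")],
    file.path(dir, "combinations.csv")
  )
  readr::write_tsv(fixture$expression, file.path(dir, "expression.tsv"))
  readr::write_tsv(
    tibble(a = fixture$ppi$edges[, 1], b = fixture$ppi$edges[, 2]),
    file.path(dir, "ppi_edges.tsv"),
    col_names = FALSE
  )
  readr::write_tsv(fixture$tissue_map, file.path(dir, "tissue_map.tsv"))
  invisible(dir)
}

#' Model configuration for the synthetic planted-rule study
#'
#' The architecture keeps its tuned defaults; the optimization budget is
#' sized to the 2,000-triplet synthetic study (up to 20 epochs with
#' early-stopping patience 4), which the companion cross-validation
#' experiments and the acceptance script share.
#'
#' @param variant model variant (see [model_config()]).
#' @param seed integer seed.
#' @param ... further overrides passed to [model_config()].
#' @return a `drugsyn_config`.
#' @export
study_model_config <- function(variant = "full", seed = 0, ...) {
  args <- utils::modifyList(
    list(variant = variant, epochs = 20, patience = 4, seed = seed),
    list(...)
  )
  do.call(model_config, args)
}
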