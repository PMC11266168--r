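# Shared fixtures, built in code and memoized per test session.

fixture_env <- new.env(parent = emptyenv())

# 30-residue helix with ss8 assigned, plus its residue graph
fixture_helix <- function() {
  if (is.null(fixture_env$helix)) {
    s <- gen_helix_structure(30, seed = 1)
    fixture_env$helix <- assign_secondary_structure(s)
  }
  fixture_env$helix
}

fixture_helix_graph <- function() {
  if (is.null(fixture_env$helix_graph)) {
    fixture_env$helix_graph <- build_residue_graph(fixture_helix())
  }
  fixture_env$helix_graph
}

# the planted-rule study dataset: 200 pairs, effect 0.4, noise 0.05
fixture_dataset <- function() {
  if (is.null(fixture_env$dataset)) {
    ds <- gen_affinity_dataset(200, planted_rule(seed = 101))
    fixture_env$dataset <- build_training_set(
      ds$records, list(HLAFIX01 = fixture_helix_graph()))
  }
  fixture_env$dataset
}

# one small trained model on the fixture (shared by attribution tests)
fixture_model <- function() {
  if (is.null(fixture_env$model)) {
    ds <- fixture_dataset()
    sub <- ds
    sub$samples <- ds$samples[seq_len(60), , drop = FALSE]
    fixture_env$model <- train_affinity_model(
      sub, gcn_config(n_epochs = 15, seed = 5))
  }
  fixture_env$model
}

fixture_peptide <- function(seq = "FAGKSHWTV") {
  key <- paste0("pep_", seq)
  if (is.null(fixture_env[[key]])) {
    fixture_env[[key]] <- suppressWarnings(build_peptide_graph(seq))
  }
  fixture_env[[key]]
}

# a minimal hand-written PDB with one alanine (5 atoms)
write_single_ala_pdb <- function(path) {
  writeLines(c(
    "ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00  0.00           N",
    "ATOM      2  CA  ALA A   1       1.458   0.000   0.000  1.00  0.00           C",
    "ATOM      3  C   ALA A   1       2.009   1.420   0.000  1.00  0.00           C",
    "ATOM      4  O   ALA A   1       1.251   2.390   0.000  1.00  0.00           O",
    "ATOM      5  CB  ALA A   1       1.988  -0.773  -1.199  1.00  0.00           C",
    "END"), path)
  path
}

# independent dense evaluation of one GCN layer, written as explicit
# loops so it shares no code with the implementation
dense_gcn_oracle <- function(edges, H, W) {
  n <- nrow(H)
  A <- matrix(0, n, n)
  if (nrow(edges)) {
    for (r in seq_len(nrow(edges))) {
      A[edges$i[r], edges$j[r]] <- 1
      A[edges$j[r], edges$i[r]] <- 1
    }
  }
  Ahat <- A + diag(n)
  deg <- rowSums(Ahat)
  Abar <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      Abar[i, j] <- Ahat[i, j] / sqrt(deg[i] * deg[j])
    }
  }
  Z <- Abar %*% H %*% W
  ifelse(Z > 0, Z, 0)
}

# restore the i < j storage convention after relabeling nodes
new_typed_edges_for_test <- function(e) {
  lo <- pmin(e$i, e$j); hi <- pmax(e$i, e$j)
  e$i <- lo; e$j <- hi
  e
}

# random undirected edge list on n nodes (no self loops, no duplicates)
random_edges <- function(n, p = 0.4) {
  pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  keep <- stats::runif(nrow(pairs)) < p
  data.frame(i = pairs[keep, 1L], j = pairs[keep, 2L],
             distance = stats::runif(sum(keep), 1, 10))
}
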