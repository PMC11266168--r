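# Affinity transform, graph convolution against the dense oracle,
# readout, prediction contracts, and training behaviour.

test_that("log50k transform maps the anchor concentrations correctly", {
  expect_equal(ic50_to_score(50000), 0)
  expect_equal(ic50_to_score(1), 1)
  expect_equal(round(ic50_to_score(500), 4), 0.4256)
  expect_error(ic50_to_score(0), "positive")
  expect_error(ic50_to_score(-5), "positive")
})

test_that("transform and inverse round-trip at high precision", {
  set.seed(1)
  y <- stats::runif(200)
  back <- ic50_to_score(score_to_ic50(y))
  expect_lt(max(abs(back - y) / pmax(y, 1e-12)), 1e-9)
})

test_that("binder classification is strict at the 500 nM cutoff", {
  expect_equal(classify_binder(0.5), "binder")
  expect_equal(classify_binder(0.3), "nonbinder")
  # exactly 500 nM is a nonbinder (strictly-greater rule)
  expect_equal(classify_binder(ic50_to_score(500)), "nonbinder")
  expect_equal(classify_binder(ic50_to_score(499.99)), "binder")
})

test_that("normalized adjacency matches hand-computed small cases", {
  # isolated node
  expect_equal(normalize_adjacency(data.frame(i = integer(),
                                              j = integer()), 1L),
               matrix(1, 1L, 1L))
  # two nodes, one edge: Ahat = ones(2), Dhat = diag(2, 2)
  A2 <- normalize_adjacency(data.frame(i = 1L, j = 2L), 2L)
  expect_equal(A2, matrix(0.5, 2L, 2L))
  # symmetry holds with arbitrary edges
  set.seed(3)
  e <- random_edges(7)
  A <- normalize_adjacency(e, 7L)
  expect_identical(A, t(A))
  Ad <- normalize_adjacency(e, 7L, edge_weight_mode = "distance_inverse")
  expect_identical(Ad, t(Ad))
  expect_error(normalize_adjacency(data.frame(i = 1L, j = 1L), 2L),
               "self-loops")
})

test_that("gcn_layer equals the dense brute-force oracle on seeded graphs", {
  set.seed(42)
  worst <- 0
  for (trial in seq_len(100L)) {
    n <- sample(2:10, 1L)
    cin <- sample(2:6, 1L)
    cout <- sample(2:6, 1L)
    e <- random_edges(n)
    H <- matrix(stats::rnorm(n * cin), n, cin)
    W <- matrix(stats::rnorm(cin * cout), cin, cout)
    got <- gcn_layer(H, normalize_adjacency(e, n), W)
    want <- dense_gcn_oracle(e, H, W)
    worst <- max(worst, max(abs(got - want)))
  }
  expect_lt(worst, 1e-6)
})

test_that("gcn_layer propagates identity and zero weights as expected", {
  x <- matrix(c(0.5, 1.2, 0.1), 1L)
  expect_equal(gcn_layer(x, matrix(1, 1L, 1L), diag(3L)), x,
               ignore_attr = TRUE)
  expect_equal(gcn_layer(x, matrix(1, 1L, 1L), matrix(0, 3L, 2L)),
               matrix(0, 1L, 2L))
  expect_error(gcn_layer(x, matrix(1, 1L, 1L), matrix(0, 2L, 2L)),
               "shape mismatch")
})

test_that("readout is permutation-invariant in all modes", {
  set.seed(5)
  H <- matrix(stats::rnorm(24), 6L, 4L)
  perm <- sample(6L)
  for (mode in c("mean", "sum", "max")) {
    expect_equal(graph_readout(H, mode), graph_readout(H[perm, ], mode))
  }
  expect_equal(graph_readout(H[2L, , drop = FALSE], "max"), H[2L, ])
  expect_equal(graph_readout(rbind(H[1L, ], H[1L, ]), "mean"), H[1L, ])
})

test_that("prediction is deterministic and permutation-invariant", {
  g <- fixture_helix_graph()
  p <- fixture_peptide()
  m <- fixture_model()
  s1 <- predict_affinity(m, g, p)
  expect_identical(s1, predict_affinity(m, g, p))
  expect_true(s1 >= 0 && s1 <= 1)

  # consistent relabeling of both graphs leaves the score unchanged
  permute_graph <- function(gr) {
    n <- nrow(gr$X)
    perm <- rev(seq_len(n))
    out <- gr
    out$X <- gr$X[perm, , drop = FALSE]
    ed <- if (inherits(gr, "residue_graph")) "edges" else "bonds"
    e <- gr[[ed]]
    e$i <- match(gr[[ed]]$i, perm)
    e$j <- match(gr[[ed]]$j, perm)
    lo <- pmin(e$i, e$j); hi <- pmax(e$i, e$j)
    e$i <- lo; e$j <- hi
    out[[ed]] <- e
    if (!is.null(out$node_ids)) {
      out$node_ids <- gr$node_ids[perm, , drop = FALSE]
    }
    out
  }
  expect_equal(predict_affinity(m, permute_graph(g), permute_graph(p)), s1,
               tolerance = 1e-12)
})

test_that("feature-width mismatches raise contract errors", {
  m <- fixture_model()
  g <- fixture_helix_graph()
  p <- fixture_peptide()
  gbad <- g
  gbad$X <- g$X[, -1L, drop = FALSE]
  expect_error(predict_affinity(m, gbad, p), "feature-width mismatch")
  pbad <- p
  pbad$X <- cbind(p$X, 0)
  expect_error(predict_affinity(m, g, pbad), "feature-width mismatch")
})

test_that("a zero-weight model predicts its output bias", {
  m <- init_affinity_model(gcn_config(seed = 3))
  for (k in seq_along(m$mlp)) m$mlp[[k]]$W[] <- 0
  m$mlp[[4L]]$b <- 0.37
  expect_equal(predict_affinity(m, fixture_helix_graph(),
                                fixture_peptide()), 0.37)
})

test_that("training reduces the loss and is seed-reproducible", {
  ds <- fixture_dataset()
  sub <- ds
  sub$samples <- ds$samples[seq_len(50), , drop = FALSE]
  cfg <- gcn_config(n_epochs = 12, seed = 21)
  m1 <- train_affinity_model(sub, cfg)
  expect_length(m1$training_history, 12L)
  expect_lt(m1$training_history[12L], m1$training_history[1L])
  m2 <- train_affinity_model(sub, cfg)
  expect_identical(m1$training_history, m2$training_history)
  expect_identical(m1$mlp, m2$mlp)
  # constant targets are learnable
  const <- sub
  const$samples$y <- 0.62
  mc <- train_affinity_model(const, gcn_config(n_epochs = 8, seed = 2))
  expect_lt(tail(mc$training_history, 1L), mc$training_history[1L])
  expect_error(train_affinity_model(list(), cfg), "empty")
})

test_that("planted-rule training halves the first-epoch MSE by epoch 50", {
  ds <- fixture_dataset()
  m <- train_affinity_model(ds, gcn_config(n_epochs = 50, seed = 13))
  expect_lt(m$training_history[50L], 0.5 * m$training_history[1L])
})

test_that("model checkpoints round-trip through JSON", {
  m <- fixture_model()
  path <- withr::local_tempfile(fileext = ".json")
  save_affinity_model(m, path)
  m2 <- load_affinity_model(path)
  g <- fixture_helix_graph()
  p <- fixture_peptide()
  expect_equal(predict_affinity(m2, g, p), predict_affinity(m, g, p),
               tolerance = 1e-12)
  expect_equal(m2$training_history, m$training_history)
  expect_error(load_affinity_model(withr::local_tempfile(
    fileext = ".json", lines = "{}")), "checkpoint")
})

test_that("config invariants are enforced", {
  expect_error(gcn_config(dropout = 1), "dropout")
  expect_error(gcn_config(mlp_dims = c(8L, 8L)), "mlp_dims")
  expect_error(gcn_config(hla_layer_dims = integer()), "hla_layer_dims")
})
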