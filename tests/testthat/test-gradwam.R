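# Gradient-weighted activation mapping: analytic gradients against finite
# differences, the alpha coefficients, score properties, the occlusion
# oracle, and structure annotation.

test_that("captured first partials match central finite differences", {
  # 5-node toy graph on the HLA branch of a trained small model
  m <- fixture_model()
  g <- fixture_helix_graph()
  p <- fixture_peptide()
  for (branch in c("hla", "peptide")) {
    fm <- capture_feature_map(m, g, p, branch)
    set.seed(17)
    # probe a random subset of entries to keep the oracle cheap
    probe <- cbind(sample(nrow(fm$T), 12L, replace = TRUE),
                   sample(ncol(fm$T), 12L, replace = TRUE))
    h <- 1e-4
    for (r in seq_len(nrow(probe))) {
      i <- probe[r, 1L]; c <- probe[r, 2L]
      Tp <- fm$T; Tp[i, c] <- Tp[i, c] + h
      Tm <- fm$T; Tm[i, c] <- Tm[i, c] - h
      fd <- (predict_from_feature_map(m, fm, Tp) -
               predict_from_feature_map(m, fm, Tm)) / (2 * h)
      denom <- max(abs(fd), abs(fm$grad1[i, c]), 1e-8)
      expect_lt(abs(fd - fm$grad1[i, c]) / denom, 1e-4)
    }
  }
})

test_that("second partials vanish for the piecewise-linear head", {
  m <- fixture_model()
  fm <- capture_feature_map(m, fixture_helix_graph(), fixture_peptide(),
                            "peptide")
  expect_true(all(fm$grad2 == 0))
  # finite differences of the first partials agree (away from kinks)
  h <- 1e-3
  i <- 3L; c <- 2L
  Tp <- fm$T; Tp[i, c] <- Tp[i, c] + h
  Tm <- fm$T; Tm[i, c] <- Tm[i, c] - h
  fd2 <- (predict_from_feature_map(m, fm, Tp) -
            2 * predict_from_feature_map(m, fm, fm$T) +
            predict_from_feature_map(m, fm, Tm)) / h^2
  expect_lt(abs(fd2), 1e-6)
})

test_that("repeated captures are identical in evaluation mode", {
  m <- fixture_model()
  g <- fixture_helix_graph()
  p <- fixture_peptide()
  fm1 <- capture_feature_map(m, g, p, "hla")
  fm2 <- capture_feature_map(m, g, p, "hla")
  expect_identical(fm1$T, fm2$T)
  expect_identical(fm1$grad1, fm2$grad1)
  expect_identical(fm1$P, fm2$P)
})

test_that("alpha reduces to 1 under a linear head and guards 0/0", {
  m <- fixture_model()
  fm <- capture_feature_map(m, fixture_helix_graph(), fixture_peptide(),
                            "peptide")
  # grad2 = 0, so wherever grad1 != 0 alpha = g/g = 1, and the eps-guard
  # fills the 0/0 entries with 1 as well
  a <- alpha_coefficients(fm)
  expect_true(all(a == 1))
  # hand-built case: grad1 = 2, T = 3, grad2 = 1 -> alpha = 2/5
  fm2 <- fm
  fm2$grad1 <- matrix(2, 1L, 1L)
  fm2$T <- matrix(3, 1L, 1L)
  fm2$grad2 <- matrix(1, 1L, 1L)
  expect_equal(alpha_coefficients(fm2), matrix(0.4, 1L, 1L))
})

test_that("zero-weight models give all-zero scores; degenerate min-max warns", {
  cfg <- gcn_config(seed = 2)
  m <- init_affinity_model(cfg)
  for (k in seq_along(m$mlp)) { m$mlp[[k]]$W[] <- 0; m$mlp[[k]]$b[] <- 0 }
  expect_warning(
    at <- gradwam_scores(m, fixture_helix_graph(), fixture_peptide(),
                         "peptide"),
    "all node scores equal")
  expect_true(all(at$raw == 0))
  expect_true(all(at$normalized == 0))
})

test_that("scores are invariant under node relabeling", {
  m <- fixture_model()
  g <- fixture_helix_graph()
  p <- fixture_peptide()
  at <- gradwam_scores(m, g, p, "peptide")
  perm <- rev(seq_len(nrow(p$X)))
  p2 <- p
  p2$X <- p$X[perm, , drop = FALSE]
  e <- p$bonds
  e$i <- match(p$bonds$i, perm); e$j <- match(p$bonds$j, perm)
  lo <- pmin(e$i, e$j); hi <- pmax(e$i, e$j); e$i <- lo; e$j <- hi
  p2$bonds <- e
  p2$atom_to_residue <- p$atom_to_residue[perm, , drop = FALSE]
  at2 <- gradwam_scores(m, g, p2, "peptide")
  expect_equal(at2$raw, at$raw[perm], tolerance = 1e-10)
  expect_equal(at2$omega, at$omega, tolerance = 1e-10)
})

test_that("occlusion gives zero deltas for zero-weight models and respects symmetry", {
  m <- init_affinity_model(gcn_config(seed = 4))
  for (k in seq_along(m$mlp)) { m$mlp[[k]]$W[] <- 0; m$mlp[[k]]$b[] <- 0 }
  oc <- occlusion_scores(m, fixture_helix_graph(), fixture_peptide(),
                         "peptide")
  expect_true(all(oc == 0))

  # identical isolated nodes get identical deltas
  mt <- fixture_model()
  g <- fixture_helix_graph()
  gi <- g
  gi$X <- rbind(g$X[1:2, , drop = FALSE], g$X[1:2, , drop = FALSE])
  gi$X[3:4, ] <- gi$X[1:2, ]
  gi$edges <- data.frame(i = integer(), j = integer(),
                         bond_type = character(), distance = numeric())
  gi$node_ids <- data.frame(chain_id = "A", seq_index = 1:4)
  oc2 <- occlusion_scores(mt, gi, fixture_peptide(), "hla")
  expect_equal(oc2[1L], oc2[3L], tolerance = 1e-12)
  expect_equal(oc2[2L], oc2[4L], tolerance = 1e-12)
})

test_that("annotated structures carry scores in the B-factor column", {
  m <- fixture_model()
  s <- fixture_helix()
  g <- fixture_helix_graph()
  at <- gradwam_scores(m, g, fixture_peptide(), "hla")
  path <- withr::local_tempfile(fileext = ".pdb")
  annotate_structure(s, at, path)
  pdb <- bio3d::read.pdb(path, verbose = FALSE)
  ca <- pdb$atom[pdb$atom$elety == "CA", ]
  expect_equal(ca$b, round(100 * at$normalized, 2L), tolerance = 1e-8)
  # the top residue carries exactly 100.00
  expect_equal(max(ca$b), 100)
  # id mismatch errors
  at_bad <- at
  at_bad$node_ids[1L] <- "Z:999"
  expect_error(annotate_structure(s, at_bad, path), "not in the structure")
})

test_that("attribution CSV output has the documented columns", {
  m <- fixture_model()
  at <- gradwam_scores(m, fixture_helix_graph(), fixture_peptide(), "hla")
  path <- withr::local_tempfile(fileext = ".csv")
  write_attribution_csv(at, path)
  df <- utils::read.csv(path)
  expect_named(df, c("node_id", "chain", "resnum", "raw", "normalized"))
  expect_equal(nrow(df), 30L)
})
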