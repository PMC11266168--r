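# Residue featurization, typed edge detectors, and graph assembly.

test_that("residue features have the fixed 43-wide block layout", {
  blocks <- residue_feature_blocks()
  expect_identical(sum(blocks), 43L)
  expect_identical(blocks[["blosum"]], 21L)
  expect_identical(blocks[["ss"]], 8L)

  f <- encode_residue("A", "H", c(1, 2, 3))
  expect_length(f, 43L)
  # alanine: no side-chain donor/acceptor
  expect_equal(unname(f[paste0("da_", c("donor", "acceptor", "both",
                                        "neither"))]),
               c(0, 0, 0, 1))
  expect_equal(sum(f[startsWith(names(f), "ss_")]), 1)
  expect_equal(unname(f["ss_H"]), 1)
  expect_equal(unname(f[c("ca_x", "ca_y", "ca_z")]), c(1, 2, 3))
})

test_that("donor/acceptor classes follow the side-chain chemistry table", {
  pick <- function(code) {
    f <- encode_residue(code, "C", c(0, 0, 0))
    names(f)[startsWith(names(f), "da_")][
      which(f[startsWith(names(f), "da_")] == 1)]
  }
  expect_equal(pick("N"), "da_both")    # amide side chain
  expect_equal(pick("R"), "da_donor")
  expect_equal(pick("K"), "da_donor")
  expect_equal(pick("W"), "da_donor")
  expect_equal(pick("D"), "da_acceptor")
  expect_equal(pick("E"), "da_acceptor")
  for (code in c("Q", "H", "S", "T", "Y")) {
    expect_equal(pick(code), "da_both")
  }
  expect_equal(pick("G"), "da_neither")
})

test_that("unknown residues use the 21st BLOSUM slot", {
  f <- encode_residue("X", "C", c(0, 0, 0))
  expect_length(f, 43L)
  # the X row of BLOSUM62 has its maximum nowhere above -1 except vs X
  expect_equal(unname(f["blosum_X"]), -0.1)
  expect_error(encode_residue("Z", "C", c(0, 0, 0)), "featurize")
  expect_error(encode_residue("A", "C", c(0, 0, NA)), "CA coordinate")
})

test_that("peptide bonds link consecutive residues within chains", {
  s <- fixture_helix()
  e <- detect_peptide_bonds(s)
  expect_equal(nrow(e), 29L)
  expect_true(all(e$bond_type == "PEPTIDE"))
  expect_true(all(e$j - e$i == 1L))
  expect_true(all(e$distance > 0 & e$distance <= 1.8))

  # two chains of 5: edges never cross the chain break
  h5 <- gen_helix_structure(5, seed = 2, chain_id = "A")
  h5b <- gen_helix_structure(5, seed = 3, chain_id = "B")
  h5b$residues$chain_id <- "B"
  h5b$atoms$x <- h5b$atoms$x + 50
  comb <- protein_structure("two_chain",
                            rbind(h5$residues, h5b$residues),
                            rbind(h5$atoms,
                                  transform(h5b$atoms,
                                            res_idx = res_idx + 5L)))
  e2 <- detect_peptide_bonds(comb)
  expect_equal(nrow(e2), 8L)
  expect_false(any(e2$i <= 5L & e2$j > 5L))
})

test_that("disulfide and ionic detectors fire on constructed geometry", {
  s <- gen_helix_structure(20, seed = 4, disulfide_pairs = list(c(3, 7)),
                           ionic_pairs = list(c(10, 14)))
  ss <- detect_disulfide_bonds(s)
  expect_equal(nrow(ss), 1L)
  expect_equal(sort(c(ss$i, ss$j)), c(3L, 7L))
  expect_equal(ss$distance, 2.04, tolerance = 1e-6)

  io <- detect_ionic_bonds(s)
  expect_equal(nrow(io), 1L)
  expect_equal(sort(c(io$i, io$j)), c(10L, 14L))
  expect_equal(io$distance, 3.5, tolerance = 1e-6)
})

test_that("hydrogen bonds respect the peptide-bond exclusion", {
  # two residues, peptide-bonded, backbone N-O well under 3.5 A
  residues <- data.frame(chain_id = "A", seq_index = 1:2,
                         name3 = c("GLY", "GLY"), code1 = "G",
                         ss8 = "C", stringsAsFactors = FALSE)
  atoms <- data.frame(
    res_idx = c(1L, 1L, 1L, 2L, 2L, 2L),
    name = c("N", "CA", "C", "N", "CA", "O"),
    element = c("N", "C", "C", "N", "C", "O"),
    x = c(0, 1.4, 2.4, 3.7, 5.1, 6.0),
    y = 0, z = 0, occupancy = 1, stringsAsFactors = FALSE)
  s <- protein_structure("pair", residues, atoms)
  expect_equal(nrow(detect_peptide_bonds(s)), 1L)
  expect_equal(nrow(detect_hydrogen_bonds(s)), 0L)

  # break the peptide bond (C1-N2 far apart) but leave the backbone O of
  # residue 2 within hydrogen-bond range of N1
  atoms2 <- atoms
  atoms2[atoms2$name == "N" & atoms2$res_idx == 2L, "x"] <- 10.0
  atoms2[atoms2$name == "CA" & atoms2$res_idx == 2L, "x"] <- 11.4
  atoms2[atoms2$name == "O", "x"] <- 3.0
  s2 <- protein_structure("pair2", residues, atoms2)
  expect_equal(nrow(detect_peptide_bonds(s2)), 0L)
  hb <- detect_hydrogen_bonds(s2)
  expect_gte(nrow(hb), 1L)
  expect_true(all(hb$bond_type == "HYDROGEN"))
})

test_that("build_residue_graph assembles nodes, features and edges", {
  g <- fixture_helix_graph()
  expect_s3_class(g, "residue_graph")
  expect_identical(dim(g$X), c(30L, 43L))
  expect_gte(nrow(g$edges), 29L)
  expect_identical(g$node_ids$seq_index, 1:30)
  # determinism
  g2 <- build_residue_graph(fixture_helix())
  expect_identical(g, g2)
  # empty chain selection errors
  expect_error(build_residue_graph(fixture_helix(),
                                   chain_policy = "single:B"),
               "empty graph")
})

test_that("translating coordinates changes only the position block", {
  s <- fixture_helix()
  s2 <- s
  s2$atoms$x <- s2$atoms$x + 11.5
  s2$atoms$y <- s2$atoms$y - 3.25
  s2$atoms$z <- s2$atoms$z + 100
  g <- build_residue_graph(s)
  g2 <- build_residue_graph(s2)
  expect_identical(g$edges[, c("i", "j", "bond_type")],
                   g2$edges[, c("i", "j", "bond_type")])
  expect_equal(g$edges$distance, g2$edges$distance, tolerance = 1e-9)
  pos_cols <- which(colnames(g$X) %in% c("ca_x", "ca_y", "ca_z"))
  expect_identical(g$X[, -pos_cols], g2$X[, -pos_cols])
  expect_equal(g2$X[, pos_cols],
               sweep(g$X[, pos_cols], 2L, c(-11.5, 3.25, -100)),
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("edge lists produce symmetric adjacency with invariant degrees", {
  g <- fixture_helix_graph()
  A <- normalize_adjacency(g$edges, n_nodes(g))
  expect_identical(A, t(A))
  set.seed(9)
  perm <- sample(n_nodes(g))
  pe <- g$edges
  pe$i <- match(g$edges$i, perm)
  pe$j <- match(g$edges$j, perm)
  Ap <- normalize_adjacency(new_typed_edges_for_test(pe), n_nodes(g))
  expect_equal(sort(rowSums(Ap > 0)), sort(rowSums(A > 0)))
})

test_that("graph JSON serialization round-trips losslessly", {
  g <- fixture_helix_graph()
  path <- withr::local_tempfile(fileext = ".json")
  write_graph_json(g, path)
  g2 <- read_graph_json(path)
  expect_equal(g2$X, g$X)
  expect_equal(g2$edges$distance, g$edges$distance)
  expect_equal(g2$node_ids$seq_index, g$node_ids$seq_index)

  p <- fixture_peptide()
  path2 <- withr::local_tempfile(fileext = ".json")
  write_graph_json(p, path2)
  p2 <- read_graph_json(path2)
  expect_equal(p2$X, p$X)
  expect_equal(p2$bonds, p$bonds, ignore_attr = TRUE)
})
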