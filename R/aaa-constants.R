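# Frozen amino-acid and featurization constants shared across modules.

# The 20 standard residues in the fixed ordering used by the BLOSUM62 block
# (Biostrings row order), plus the unknown channel 'X' as slot 21.
AA_ORDER <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
              "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

AA_3TO1 <- c(
  ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
  GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
  LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
  SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V",
  # common variants seen in PDB files; mapped to their parent where standard
  MSE = "M", SEC = "X", PYL = "X", UNK = "X"
)

AA_1TO3 <- c(
  A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS",
  Q = "GLN", E = "GLU", G = "GLY", H = "HIS", I = "ILE",
  L = "LEU", K = "LYS", M = "MET", F = "PHE", P = "PRO",
  S = "SER", T = "THR", W = "TRP", Y = "TYR", V = "VAL"
)

# Eight-state secondary structure alphabet, fixed one-hot order.
SS8_STATES <- c("H", "B", "E", "T", "G", "I", "S", "C")

# Hydrogen donor/acceptor class of the side chain. One-hot order:
# donor, acceptor, both, neither.
DONOR_CLASS_ORDER <- c("donor", "acceptor", "both", "neither")
AA_DONOR_CLASS <- local({
  cls <- rep("neither", 20)
  names(cls) <- AA_ORDER
  cls[c("R", "K", "W")] <- "donor"
  cls[c("D", "E")] <- "acceptor"
  cls[c("N", "Q", "H", "S", "T", "Y")] <- "both"
  cls
})

# Seven physicochemical descriptors per residue (the parameterization of
# Meiler et al. 2001, J Mol Model 7:360-369), columns reordered to:
# steric parameter, hydrophobicity, volume, polarizability, isoelectric
# point, helix probability, sheet probability.
AAPHY7 <- local({
  m <- rbind(
    #     steric hydroph  volume polariz  pI    helixP sheetP
    A = c(1.28,  0.31,    1.00,  0.05,    6.11, 0.42,  0.23),
    R = c(2.34, -1.01,    6.13,  0.29,   10.74, 0.36,  0.25),
    N = c(1.60, -0.60,    2.95,  0.13,    6.52, 0.21,  0.22),
    D = c(1.60, -0.77,    2.78,  0.11,    2.95, 0.25,  0.20),
    C = c(1.77,  1.54,    2.43,  0.13,    6.35, 0.17,  0.41),
    Q = c(1.56, -0.22,    3.95,  0.18,    5.65, 0.36,  0.25),
    E = c(1.56, -0.64,    3.78,  0.15,    3.09, 0.42,  0.21),
    G = c(0.00,  0.00,    0.00,  0.00,    6.07, 0.13,  0.15),
    H = c(2.99,  0.13,    4.66,  0.23,    7.69, 0.27,  0.30),
    I = c(4.19,  1.80,    4.00,  0.19,    6.04, 0.30,  0.45),
    L = c(2.59,  1.70,    4.00,  0.19,    6.04, 0.39,  0.31),
    K = c(1.89, -0.99,    4.77,  0.22,    9.99, 0.32,  0.27),
    M = c(2.35,  1.23,    4.43,  0.22,    5.71, 0.38,  0.32),
    F = c(2.94,  1.79,    5.89,  0.29,    5.67, 0.30,  0.38),
    P = c(2.67,  0.72,    2.72,  0.00,    6.80, 0.13,  0.34),
    S = c(1.31, -0.04,    1.60,  0.06,    5.70, 0.20,  0.28),
    T = c(3.03,  0.26,    2.60,  0.11,    5.60, 0.21,  0.36),
    W = c(3.21,  2.25,    8.08,  0.41,    5.94, 0.32,  0.42),
    Y = c(2.94,  0.96,    6.47,  0.30,    5.66, 0.25,  0.41),
    V = c(3.67,  1.22,    3.00,  0.14,    6.02, 0.27,  0.49)
  )
  colnames(m) <- c("steric", "hydrophobicity", "volume", "polarizability",
                   "isoelectric", "helix_prob", "sheet_prob")
  # unknown residues get the 20-residue mean
  rbind(m, X = colMeans(m))
})

# Side-chain SMILES fragments, attached at the beta carbon, no stereocenters.
# Glycine has no side chain; proline is assembled as a special cyclic unit.
AA_SIDECHAIN_SMILES <- c(
  A = "C",
  R = "CCCNC(=N)N",
  N = "CC(=O)N",
  D = "CC(=O)O",
  C = "CS",
  Q = "CCC(=O)N",
  E = "CCC(=O)O",
  G = "",
  H = "Cc1c[nH]cn1",
  I = "C(C)CC",
  L = "CC(C)C",
  K = "CCCCN",
  M = "CCSC",
  F = "Cc1ccccc1",
  P = NA,  # handled as a ring with the backbone nitrogen
  S = "CO",
  T = "C(C)O",
  W = "Cc1c[nH]c2ccccc12",
  Y = "Cc1ccc(O)cc1",
  V = "C(C)C"
)

# Heavy-atom counts of the free amino acids (used for condensation counting:
# a peptide of length L has sum(per-residue) - (L - 1) heavy atoms).
AA_HEAVY_ATOMS <- c(
  A = 6, R = 12, N = 9, D = 9, C = 7, Q = 10, E = 10, G = 5, H = 11, I = 9,
  L = 9, K = 10, M = 9, F = 12, P = 8, S = 7, T = 8, W = 15, Y = 13, V = 8
)

# Table-4 atom featurization layout (width 22).
ATOM_ELEMENT_ORDER <- c("H", "C", "N", "O", "F", "Cl", "S", "Br", "I")
ATOM_HYBRIDIZATIONS <- c("sp", "sp2", "sp3")
ATOM_DEFAULT_VALENCE <- c(H = 1, C = 4, N = 3, O = 2, F = 1,
                          Cl = 1, S = 2, Br = 1, I = 1)

RESIDUE_FEATURE_WIDTH <- 43L  # 21 + 8 + 3 + 4 + 7
ATOM_FEATURE_WIDTH <- 22L     # 9 + 1+1+1 + 3 + 1+1+1+1+1+1

# BLOSUM62 rows over (20 standard + X), integer substitution scores.
# Pulled once from Biostrings and cached.
blosum62_rows <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      e <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = e)
      sel <- c(AA_ORDER, "X")
      cache <<- e$BLOSUM62[sel, sel, drop = FALSE]
    }
    cache
  }
})

#' Residue-feature block layout
#'
#' Names and widths of the five feature blocks of the residue-level graph
#' (BLOSUM62 row, secondary-structure one-hot, alpha-carbon position,
#' donor/acceptor class one-hot, physicochemical descriptors).
#'
#' @return Named integer vector of block widths summing to 43.
#' @export
residue_feature_blocks <- function() {
  c(blosum = 21L, ss = 8L, position = 3L, donor_acceptor = 4L, aaphy7 = 7L)
}

#' Atom-feature block layout
#'
#' Names and widths of the atom feature blocks of the peptide molecular
#' graph (element one-hot, atomic number, acceptor/donor/aromatic flags,
#' hybridization one-hot, hydrogen counts, charge, valences, radicals).
#'
#' @return Named integer vector of block widths summing to 22.
#' @export
atom_feature_blocks <- function() {
  c(element = 9L, atomic_num = 1L, acceptor = 1L, donor = 1L, aromatic = 1L,
    hybridization = 3L, n_hydrogens = 1L, formal_charge = 1L,
    explicit_valence = 1L, implicit_valence = 1L, n_implicit_h = 1L,
    n_radical_electrons = 1L)
}
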