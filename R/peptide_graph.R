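# Peptide sequence -> SMILES assembly -> atom-level molecular graph with
# the 22-dimensional atom featurization and integer bond orders.

ATOMIC_NUMBERS <- c(H = 1, B = 5, C = 6, N = 7, O = 8, F = 9, P = 15,
                    S = 16, Cl = 17, Br = 35, I = 53, Se = 34)

#' Assemble the SMILES string of a linear peptide
#'
#' The peptide is built by condensation of one backbone unit
#' `N-CA(-side chain)-C(=O)` per residue from a frozen side-chain fragment
#' map of the 20 standard amino acids (proline as a ring through the
#' backbone nitrogen), with a free N-terminus and a carboxylate C-terminus.
#' No stereochemistry is emitted. The output is deterministic.
#'
#' @param seq One-letter peptide string (standard 20 residues).
#' @return A SMILES string.
#' @export
peptide_to_smiles <- function(seq) {
  aa <- strsplit(seq, "")[[1L]]
  if (!length(aa)) {
    stop("unsupported residue: empty peptide sequence", call. = FALSE)
  }
  bad <- setdiff(aa, AA_ORDER)
  if (length(bad)) {
    stop("unsupported residue code(s): ", paste(unique(bad), collapse = ", "),
         call. = FALSE)
  }
  unit <- vapply(aa, function(a) {
    if (a == "G") return("NCC(=O)")
    if (a == "P") return("N1CCCC1C(=O)")
    paste0("NC(", AA_SIDECHAIN_SMILES[[a]], ")C(=O)")
  }, character(1L))
  paste0(paste(unit, collapse = ""), "O")
}

# heavy atoms contributed by residue r of an in-chain peptide
peptide_unit_sizes <- function(aa, terminal_oh = TRUE) {
  sizes <- AA_HEAVY_ATOMS[aa] - 1L
  if (terminal_oh) sizes[length(sizes)] <- sizes[length(sizes)] + 1L
  unname(sizes)
}

# --- minimal parsers for the two OpenBabel outputs ------------------------

parse_molfile <- function(txt) {
  lines <- strsplit(txt, "\n", fixed = TRUE)[[1L]]
  if (length(lines) < 4L) stop("SMILES parse error: empty molecule",
                               call. = FALSE)
  counts <- lines[4L]
  na <- suppressWarnings(as.integer(substr(counts, 1L, 3L)))
  nb <- suppressWarnings(as.integer(substr(counts, 4L, 6L)))
  if (is.na(na) || na < 1L) stop("SMILES parse error: no atoms",
                                 call. = FALSE)
  ablock <- lines[5L:(4L + na)]
  element <- trimws(substr(ablock, 32L, 34L))
  bonds <- if (nb > 0L) {
    bblock <- lines[(5L + na):(4L + na + nb)]
    data.frame(
      i = as.integer(substr(bblock, 1L, 3L)),
      j = as.integer(substr(bblock, 4L, 6L)),
      order = as.integer(substr(bblock, 7L, 9L))
    )
  } else {
    data.frame(i = integer(), j = integer(), order = integer())
  }
  charge <- rep(0L, na)
  for (l in grep("^M  CHG", lines, value = TRUE)) {
    f <- as.integer(strsplit(trimws(sub("^M  CHG", "", l)), "\\s+")[[1L]])
    k <- f[1L]
    for (p in seq_len(k)) {
      charge[f[2L * p]] <- f[2L * p + 1L]
    }
  }
  list(element = element, bonds = bonds, charge = charge)
}

parse_mol2_aromatic <- function(txt) {
  lines <- strsplit(txt, "\n", fixed = TRUE)[[1L]]
  a0 <- grep("^@<TRIPOS>ATOM", lines)
  if (!length(a0)) return(NULL)
  stop_at <- grep("^@<TRIPOS>", lines)
  stop_at <- stop_at[stop_at > a0[1L]]
  end <- if (length(stop_at)) stop_at[1L] - 1L else length(lines)
  rows <- lines[(a0[1L] + 1L):end]
  rows <- rows[nzchar(trimws(rows))]
  fields <- strsplit(trimws(rows), "\\s+")
  vapply(fields, function(f) grepl("\\.ar$", f[6L]), logical(1L))
}

#' Convert a SMILES string to an atom-level graph
#'
#' The molecule is parsed and kekulized through OpenBabel, so every bond
#' carries an integer order (single/double/triple); aromaticity survives as
#' a per-atom flag. By default a heavy-atom graph is built and hydrogens
#' are folded into the per-atom hydrogen count; with `explicit_h = TRUE`
#' hydrogen nodes are appended explicitly. Hydrogen counts and valences
#' follow standard valence rules (C4, N3, O2, S2, halogens 1, adjusted by
#' formal charge on N/O).
#'
#' Feature blocks per atom, fixed order (width 22): element one-hot over
#' H,C,N,O,F,Cl,S,Br,I (other elements encode as all-zero); atomic number;
#' acceptor flag (N/O with a free lone pair); donor flag (N/O bearing at
#' least one hydrogen); aromatic flag; hybridization one-hot (sp, sp2,
#' sp3); hydrogen count; formal charge; explicit valence (sum of bond
#' orders to explicit neighbours); implicit valence (implicit hydrogens);
#' implicit hydrogen count; radical electron count.
#'
#' @param smiles A SMILES string.
#' @param explicit_h Add hydrogen atoms as graph nodes (default `FALSE`).
#' @return An object of class `atom_graph`: `atoms` data frame, feature
#'   matrix `X` (M x 22), `bonds` data frame (`i`, `j`, `order`).
#' @export
smiles_to_graph <- function(smiles, explicit_h = FALSE) {
  stopifnot(is.character(smiles), length(smiles) == 1L, nzchar(smiles))
  sdf <- tryCatch(
    suppressWarnings(ChemmineOB::convertFormat("SMI", "SDF", smiles)),
    error = function(e) stop("SMILES parse error: ", conditionMessage(e),
                             call. = FALSE)
  )
  mol <- parse_molfile(sdf)
  mol2 <- suppressWarnings(ChemmineOB::convertFormat("SMI", "MOL2", smiles))
  arom <- parse_mol2_aromatic(mol2)
  if (is.null(arom) || length(arom) != length(mol$element)) {
    arom <- rep(FALSE, length(mol$element))
  }

  n <- length(mol$element)
  elem <- mol$element
  charge <- mol$charge
  bonds <- mol$bonds

  bond_sum <- numeric(n)
  n_double <- integer(n)
  n_triple <- integer(n)
  for (r in seq_len(nrow(bonds))) {
    i <- bonds$i[r]; j <- bonds$j[r]; o <- bonds$order[r]
    bond_sum[i] <- bond_sum[i] + o
    bond_sum[j] <- bond_sum[j] + o
    if (o == 2L) { n_double[i] <- n_double[i] + 1L
                   n_double[j] <- n_double[j] + 1L }
    if (o == 3L) { n_triple[i] <- n_triple[i] + 1L
                   n_triple[j] <- n_triple[j] + 1L }
  }
  defval <- ATOM_DEFAULT_VALENCE[elem]
  defval[is.na(defval)] <- bond_sum[is.na(defval)]  # OTHER: no implicit H
  adj <- ifelse(elem %in% c("N", "O"), charge, 0L)
  n_h <- pmax(0L, as.integer(defval + adj - bond_sum))
  # sulfur in higher oxidation states: no implicit hydrogens
  n_h[elem == "S" & bond_sum > 2] <- 0L

  hybrid <- ifelse(n_triple > 0L | n_double >= 2L, "sp",
                   ifelse(n_double > 0L | arom, "sp2", "sp3"))
  donor <- elem %in% c("N", "O") & n_h >= 1L
  acceptor <- elem == "O" |
    (elem == "N" & charge <= 0L & !(arom & n_h >= 1L))

  atoms <- data.frame(
    element = elem,
    atomic_num = as.integer(ifelse(is.na(ATOMIC_NUMBERS[elem]), 0L,
                                   ATOMIC_NUMBERS[elem])),
    is_acceptor = as.integer(acceptor),
    is_donor = as.integer(donor),
    is_aromatic = as.integer(arom),
    hybridization = hybrid,
    n_hydrogens = n_h,
    formal_charge = as.integer(charge),
    explicit_valence = as.integer(bond_sum),
    implicit_valence = n_h,
    n_implicit_h = n_h,
    n_radical_electrons = 0L,
    stringsAsFactors = FALSE
  )

  if (explicit_h) {
    extra <- list(); hb <- list()
    for (i in seq_len(n)) {
      if (atoms$n_hydrogens[i] == 0L) next
      for (k in seq_len(atoms$n_hydrogens[i])) {
        extra[[length(extra) + 1L]] <- data.frame(
          element = "H", atomic_num = 1L, is_acceptor = 0L, is_donor = 0L,
          is_aromatic = 0L, hybridization = "sp3", n_hydrogens = 0L,
          formal_charge = 0L, explicit_valence = 1L, implicit_valence = 0L,
          n_implicit_h = 0L, n_radical_electrons = 0L,
          stringsAsFactors = FALSE
        )
        hb[[length(hb) + 1L]] <-
          data.frame(i = i, j = n + length(extra), order = 1L)
      }
    }
    if (length(extra)) {
      atoms$explicit_valence <- atoms$explicit_valence + atoms$n_hydrogens
      atoms$implicit_valence <- 0L
      atoms$n_implicit_h <- 0L
      atoms <- rbind(atoms, do.call(rbind, extra))
      bonds <- rbind(bonds, do.call(rbind, hb))
    }
  }

  structure(
    list(atoms = atoms, X = atom_feature_matrix(atoms), bonds = bonds),
    class = "atom_graph"
  )
}

atom_feature_matrix <- function(atoms) {
  m <- nrow(atoms)
  el <- matrix(0, m, length(ATOM_ELEMENT_ORDER))
  hit <- match(atoms$element, ATOM_ELEMENT_ORDER)
  ok <- !is.na(hit)
  el[cbind(which(ok), hit[ok])] <- 1
  hy <- matrix(0, m, 3L)
  hy[cbind(seq_len(m), match(atoms$hybridization, ATOM_HYBRIDIZATIONS))] <- 1
  X <- cbind(el, atoms$atomic_num, atoms$is_acceptor, atoms$is_donor,
             atoms$is_aromatic, hy, atoms$n_hydrogens, atoms$formal_charge,
             atoms$explicit_valence, atoms$implicit_valence,
             atoms$n_implicit_h, atoms$n_radical_electrons)
  colnames(X) <- c(paste0("elem_", ATOM_ELEMENT_ORDER), "atomic_num",
                   "is_acceptor", "is_donor", "is_aromatic",
                   paste0("hyb_", ATOM_HYBRIDIZATIONS), "n_hydrogens",
                   "formal_charge", "explicit_valence", "implicit_valence",
                   "n_implicit_h", "n_radical_electrons")
  storage.mode(X) <- "double"
  X
}

#' @export
print.atom_graph <- function(x, ...) {
  cat("<atom_graph> ", nrow(x$X), " atoms x ", ncol(x$X), " features, ",
      nrow(x$bonds), " bonds\n", sep = "")
  invisible(x)
}

#' Build the molecular graph of a peptide sequence
#'
#' Composition of [peptide_to_smiles()] and [smiles_to_graph()], with an
#' atom-to-residue map derived from the deterministic assembly order.
#' Peptides outside the usual HLA ligand length range (8-25) are accepted
#' with a warning.
#'
#' @param seq One-letter peptide string.
#' @param explicit_h Add hydrogens as nodes (default `FALSE`).
#' @return An `atom_graph` whose `atom_to_residue` data frame maps every
#'   atom to its 1-based peptide position and residue code.
#' @export
build_peptide_graph <- function(seq, explicit_h = FALSE) {
  smi <- peptide_to_smiles(seq)
  aa <- strsplit(seq, "")[[1L]]
  if (length(aa) < 8L || length(aa) > 25L) {
    warning("peptide length ", length(aa),
            " outside the usual HLA ligand range (8-25)", call. = FALSE)
  }
  g <- smiles_to_graph(smi, explicit_h = FALSE)
  sizes <- peptide_unit_sizes(aa)
  if (sum(sizes) != nrow(g$atoms)) {
    stop("internal error: assembly atom count mismatch for '", seq, "'",
         call. = FALSE)
  }
  pos <- rep(seq_along(aa), sizes)
  if (explicit_h) {
    # hydrogens are appended per heavy atom, in heavy-atom order
    hpos <- rep(pos, g$atoms$n_hydrogens)
    g <- smiles_to_graph(smi, explicit_h = TRUE)
    pos <- c(pos, hpos)
  }
  g$atom_to_residue <- data.frame(atom = seq_len(nrow(g$atoms)),
                                  position = pos, code = aa[pos],
                                  stringsAsFactors = FALSE)
  g
}

#' Read peptide sequences from a file
#'
#' Accepts FASTA (any line starting with `>`) or plain one-sequence-per-line
#' text; returns a named character vector (names from FASTA headers or
#' `pep1..pepN`).
#'
#' @param path Input file path.
#' @return Named character vector of peptide sequences.
#' @export
read_peptides <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("no sequences in ", path, call. = FALSE)
  if (any(startsWith(lines, ">"))) {
    aas <- Biostrings::readAAStringSet(path)
    out <- as.character(aas)
    names(out) <- names(aas)
  } else {
    out <- toupper(trimws(lines))
    names(out) <- paste0("pep", seq_along(out))
  }
  out
}
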