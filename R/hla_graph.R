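# Residue-level attributed graph of an HLA structure: 43-dimensional node
# features and four typed bond edges (peptide, hydrogen, ionic, disulfide).

# default geometric cutoffs (angstrom); the edge chemistry of the graph
RESIDUE_EDGE_CUTOFFS <- list(
  peptide_CN = 1.8,    # backbone C(i)-N(i+1)
  peptide_CA = 4.5,    # CA(i)-CA(i+1) fallback when backbone atoms missing
  disulfide = 2.5,     # CYS SG-SG
  ionic = 4.0,         # basic side-chain N to acidic side-chain O
  hbond = 3.5          # donor heavy atom to acceptor heavy atom
)

#' Encode one residue as a 43-dimensional feature vector
#'
#' Feature blocks in fixed order: BLOSUM62 substitution row over the 20
#' standard residues plus an unknown channel (scaled), secondary-structure
#' one-hot over H,B,E,T,G,I,S,C, raw alpha-carbon coordinates, side-chain
#' hydrogen donor/acceptor class one-hot (donor: R,K,W; acceptor: D,E;
#' both: N,Q,H,S,T,Y; otherwise neither), and seven physicochemical
#' descriptors (steric parameter, hydrophobicity, volume, polarizability,
#' isoelectric point, helix and sheet probability).
#'
#' @param code1 One-letter residue code (`"X"` for nonstandard residues,
#'   which use the unknown BLOSUM channel and mean descriptors).
#' @param ss8 Secondary-structure state, one of H,B,E,T,G,I,S,C.
#' @param ca_xyz Numeric alpha-carbon coordinate 3-vector (angstrom).
#' @param blosum_scale Multiplier applied to the integer BLOSUM62 scores to
#'   keep feature magnitudes comparable (default 0.1).
#' @return Named numeric vector of length 43.
#' @export
encode_residue <- function(code1, ss8, ca_xyz, blosum_scale = 0.1) {
  if (!code1 %in% c(AA_ORDER, "X")) {
    stop("cannot featurize residue code '", code1, "'", call. = FALSE)
  }
  if (is.null(ca_xyz) || length(ca_xyz) != 3L || !all(is.finite(ca_xyz))) {
    stop("residue ", code1, " lacks a finite CA coordinate", call. = FALSE)
  }
  if (!ss8 %in% SS8_STATES) {
    stop("residue ", code1, " has no valid ss8 label (got '", ss8, "')",
         call. = FALSE)
  }
  bl <- blosum62_rows()[code1, ] * blosum_scale
  ss <- as.numeric(SS8_STATES == ss8)
  cls <- if (code1 == "X") "neither" else AA_DONOR_CLASS[[code1]]
  da <- as.numeric(DONOR_CLASS_ORDER == cls)
  phy <- AAPHY7[code1, ]
  out <- c(bl, ss, as.numeric(ca_xyz), da, phy)
  names(out) <- c(paste0("blosum_", c(AA_ORDER, "X")),
                  paste0("ss_", SS8_STATES),
                  c("ca_x", "ca_y", "ca_z"),
                  paste0("da_", DONOR_CLASS_ORDER),
                  paste0("phy_", colnames(AAPHY7)))
  out
}

new_typed_edges <- function(i = integer(), j = integer(),
                            bond_type = character(), distance = numeric()) {
  lo <- pmin(i, j); hi <- pmax(i, j)
  data.frame(i = lo, j = hi, bond_type = bond_type, distance = distance,
             stringsAsFactors = FALSE)
}

# atoms of residue ridx matching a name set, as a coordinate matrix
res_atoms_xyz <- function(s, ridx, names_keep) {
  a <- s$atoms[s$atoms$res_idx == ridx & s$atoms$name %in% names_keep, ,
               drop = FALSE]
  if (!nrow(a)) return(NULL)
  m <- as.matrix(a[, c("x", "y", "z")])
  rownames(m) <- a$name
  m
}

min_cross_distance <- function(m1, m2) {
  d2 <- outer(rowSums(m1^2), rowSums(m2^2), "+") - 2 * (m1 %*% t(m2))
  sqrt(max(0, min(d2)))
}

#' Detect backbone peptide-bond edges
#'
#' Residues consecutive within a chain are joined when the C(i)-N(i+1)
#' distance is at most 1.8 angstrom; if either backbone atom is missing the
#' detector falls back to CA(i)-CA(i+1) at 4.5 angstrom. The measured
#' distance is stored.
#'
#' @param s A `protein_structure`.
#' @param cutoffs Geometric cutoff list (see `RESIDUE_EDGE_CUTOFFS` defaults).
#' @return Data frame of typed edges.
#' @export
detect_peptide_bonds <- function(s, cutoffs = RESIDUE_EDGE_CUTOFFS) {
  n <- n_residues(s)
  out <- list()
  for (k in seq_len(max(0L, n - 1L))) {
    if (s$residues$chain_id[k] != s$residues$chain_id[k + 1L]) next
    ci <- atom_xyz(s, k, "C"); nj <- atom_xyz(s, k + 1L, "N")
    if (!is.null(ci) && !is.null(nj)) {
      d <- sqrt(sum((ci - nj)^2))
      if (d <= cutoffs$peptide_CN) {
        out[[length(out) + 1L]] <- c(k, k + 1L, d)
      }
    } else {
      cai <- atom_xyz(s, k, "CA"); caj <- atom_xyz(s, k + 1L, "CA")
      if (!is.null(cai) && !is.null(caj)) {
        d <- sqrt(sum((cai - caj)^2))
        if (d <= cutoffs$peptide_CA) {
          out[[length(out) + 1L]] <- c(k, k + 1L, d)
        }
      }
    }
  }
  if (!length(out)) return(new_typed_edges())
  m <- do.call(rbind, out)
  new_typed_edges(as.integer(m[, 1L]), as.integer(m[, 2L]),
                  rep("PEPTIDE", nrow(m)), m[, 3L])
}

#' Detect disulfide bridges
#'
#' Cysteine pairs whose SG-SG distance is at most 2.5 angstrom.
#'
#' @inheritParams detect_peptide_bonds
#' @return Data frame of typed edges.
#' @export
detect_disulfide_bonds <- function(s, cutoffs = RESIDUE_EDGE_CUTOFFS) {
  cys <- which(s$residues$name3 == "CYS")
  out <- list()
  if (length(cys) >= 2L) {
    for (a in seq_along(cys)[-length(cys)]) {
      for (b in (a + 1L):length(cys)) {
        sg1 <- atom_xyz(s, cys[a], "SG"); sg2 <- atom_xyz(s, cys[b], "SG")
        if (is.null(sg1) || is.null(sg2)) next
        d <- sqrt(sum((sg1 - sg2)^2))
        if (d <= cutoffs$disulfide) {
          out[[length(out) + 1L]] <- c(cys[a], cys[b], d)
        }
      }
    }
  }
  if (!length(out)) return(new_typed_edges())
  m <- do.call(rbind, out)
  new_typed_edges(as.integer(m[, 1L]), as.integer(m[, 2L]),
                  rep("DISULFIDE", nrow(m)), m[, 3L])
}

IONIC_BASIC_ATOMS <- list(ARG = c("NH1", "NH2", "NE"), LYS = "NZ",
                          HIS = c("ND1", "NE2"))
IONIC_ACIDIC_ATOMS <- list(ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"))

#' Detect ionic (salt-bridge) edges
#'
#' A basic side-chain nitrogen (ARG NH1/NH2/NE, LYS NZ, HIS ND1/NE2) within
#' 4.0 angstrom of an acidic side-chain oxygen (ASP OD1/OD2, GLU OE1/OE2).
#' One edge per residue pair, the minimum distance kept.
#'
#' @inheritParams detect_peptide_bonds
#' @return Data frame of typed edges.
#' @export
detect_ionic_bonds <- function(s, cutoffs = RESIDUE_EDGE_CUTOFFS) {
  basic <- which(s$residues$name3 %in% names(IONIC_BASIC_ATOMS))
  acidic <- which(s$residues$name3 %in% names(IONIC_ACIDIC_ATOMS))
  out <- list()
  for (b in basic) {
    mb <- res_atoms_xyz(s, b, IONIC_BASIC_ATOMS[[s$residues$name3[b]]])
    if (is.null(mb)) next
    for (a in acidic) {
      if (a == b) next
      ma <- res_atoms_xyz(s, a, IONIC_ACIDIC_ATOMS[[s$residues$name3[a]]])
      if (is.null(ma)) next
      d <- min_cross_distance(mb, ma)
      if (d <= cutoffs$ionic) out[[length(out) + 1L]] <- c(b, a, d)
    }
  }
  if (!length(out)) return(new_typed_edges())
  m <- do.call(rbind, out)
  new_typed_edges(as.integer(m[, 1L]), as.integer(m[, 2L]),
                  rep("IONIC", nrow(m)), m[, 3L])
}

#' Detect hydrogen-bond edges
#'
#' Heavy-atom criterion: a donor atom (any side-chain N or O of a residue
#' whose side chain is donor-capable, plus every backbone N) within 3.5
#' angstrom of an acceptor atom (side-chain O of an acceptor-capable
#' residue, plus every backbone O). Pairs already joined by a peptide bond
#' are excluded; one edge per residue pair with the minimum distance kept.
#'
#' @inheritParams detect_peptide_bonds
#' @return Data frame of typed edges.
#' @export
detect_hydrogen_bonds <- function(s, cutoffs = RESIDUE_EDGE_CUTOFFS) {
  n <- n_residues(s)
  pep <- detect_peptide_bonds(s, cutoffs)
  bonded <- paste(pep$i, pep$j)

  donor_capable <- s$residues$code1 %in%
    names(AA_DONOR_CLASS)[AA_DONOR_CLASS %in% c("donor", "both")]
  acceptor_capable <- s$residues$code1 %in%
    names(AA_DONOR_CLASS)[AA_DONOR_CLASS %in% c("acceptor", "both")]

  donor_xyz <- function(i) {
    a <- s$atoms[s$atoms$res_idx == i, , drop = FALSE]
    keep <- a$name == "N" |
      (donor_capable[i] & a$name != "N" & a$name != "O" & a$name != "OXT" &
         substr(a$name, 1L, 1L) %in% c("N", "O"))
    if (!any(keep)) return(NULL)
    as.matrix(a[keep, c("x", "y", "z")])
  }
  acceptor_xyz <- function(i) {
    a <- s$atoms[s$atoms$res_idx == i, , drop = FALSE]
    keep <- a$name %in% c("O", "OXT") |
      (acceptor_capable[i] & !a$name %in% c("O", "OXT") &
         substr(a$name, 1L, 1L) == "O")
    if (!any(keep)) return(NULL)
    as.matrix(a[keep, c("x", "y", "z")])
  }

  don <- lapply(seq_len(n), donor_xyz)
  acc <- lapply(seq_len(n), acceptor_xyz)
  best <- new.env(parent = emptyenv())
  for (i in seq_len(n)) {
    if (is.null(don[[i]])) next
    for (j in seq_len(n)) {
      if (i == j || is.null(acc[[j]])) next
      lo <- min(i, j); hi <- max(i, j)
      if (paste(lo, hi) %in% bonded) next
      d <- min_cross_distance(don[[i]], acc[[j]])
      if (d <= cutoffs$hbond) {
        key <- paste(lo, hi)
        if (is.null(best[[key]]) || d < best[[key]][3L]) {
          best[[key]] <- c(lo, hi, d)
        }
      }
    }
  }
  vals <- mget(ls(best), envir = best)
  if (!length(vals)) return(new_typed_edges())
  m <- do.call(rbind, vals)
  m <- m[order(m[, 1L], m[, 2L]), , drop = FALSE]
  new_typed_edges(as.integer(m[, 1L]), as.integer(m[, 2L]),
                  rep("HYDROGEN", nrow(m)), m[, 3L])
}

#' Build the residue-level graph of an HLA structure
#'
#' Nodes follow structure order; each node carries the 43-dimensional
#' feature vector of [encode_residue()]; edges are the union of the four
#' typed detectors (a residue pair connected by several bond types keeps
#' one edge per type).
#'
#' @param s A `protein_structure` with ss8 assigned (see
#'   [assign_secondary_structure()]; unassigned structures are run through
#'   the geometric fallback automatically).
#' @param chain_policy `"merge_all"` (default; all chains in one graph, as
#'   for a class II alpha+beta pair) or `"single:<id>"` to keep one chain.
#' @param blosum_scale Passed to [encode_residue()].
#' @param center_coords If `TRUE`, subtract the alpha-carbon centroid from
#'   the coordinate block so features are translation-invariant (default
#'   `FALSE`: raw coordinates).
#' @param cutoffs Geometric cutoffs for the edge detectors.
#' @return An object of class `residue_graph` with elements `node_ids`
#'   (data frame `chain_id`, `seq_index`), `X` (N x 43 matrix) and `edges`.
#' @export
build_residue_graph <- function(s, chain_policy = "merge_all",
                                blosum_scale = 0.1, center_coords = FALSE,
                                cutoffs = RESIDUE_EDGE_CUTOFFS) {
  stopifnot(inherits(s, "protein_structure"))
  if (startsWith(chain_policy, "single:")) {
    ch <- sub("^single:", "", chain_policy)
    keep <- which(s$residues$chain_id == ch)
    if (!length(keep)) {
      stop("empty graph: structure has no chain '", ch, "'", call. = FALSE)
    }
    s$residues <- s$residues[keep, , drop = FALSE]
    s$atoms <- s$atoms[s$atoms$res_idx %in% keep, , drop = FALSE]
    s$atoms$res_idx <- match(s$atoms$res_idx, keep)
    s$chains <- ch
    rownames(s$residues) <- rownames(s$atoms) <- NULL
  } else if (chain_policy != "merge_all") {
    stop("chain_policy must be 'merge_all' or 'single:<id>'", call. = FALSE)
  }
  if (anyNA(s$residues$ss8)) {
    s <- assign_secondary_structure(s)
  }
  n <- n_residues(s)
  ca <- ca_matrix(s)
  if (anyNA(ca)) {
    bad <- which(apply(ca, 1L, anyNA))[1L]
    stop("residue ", s$residues$chain_id[bad], ":",
         s$residues$seq_index[bad], " has no CA; cannot featurize",
         call. = FALSE)
  }
  pos <- if (center_coords) sweep(ca, 2L, colMeans(ca)) else ca
  X <- matrix(0, n, RESIDUE_FEATURE_WIDTH)
  for (k in seq_len(n)) {
    X[k, ] <- encode_residue(s$residues$code1[k], s$residues$ss8[k],
                             pos[k, ], blosum_scale = blosum_scale)
  }
  colnames(X) <- names(encode_residue("A", "C", c(0, 0, 0)))
  edges <- rbind(
    detect_peptide_bonds(s, cutoffs),
    detect_hydrogen_bonds(s, cutoffs),
    detect_ionic_bonds(s, cutoffs),
    detect_disulfide_bonds(s, cutoffs)
  )
  rownames(edges) <- NULL
  structure(
    list(node_ids = s$residues[, c("chain_id", "seq_index"),
                               drop = FALSE],
         X = X, edges = edges),
    class = "residue_graph"
  )
}

#' @export
print.residue_graph <- function(x, ...) {
  cat("<residue_graph> ", nrow(x$X), " nodes x ", ncol(x$X),
      " features, ", nrow(x$edges), " edges (",
      paste(sprintf("%s=%d", names(table(x$edges$bond_type)),
                    as.integer(table(x$edges$bond_type))), collapse = ", "),
      ")\n", sep = "")
  invisible(x)
}

#' Number of graph nodes
#' @param g A `residue_graph` or `atom_graph`.
#' @return Integer node count.
#' @export
n_nodes <- function(g) nrow(g$X)

#' Serialize a graph to JSON
#'
#' Writes a lossless, documented JSON representation shared by residue- and
#' atom-level graphs: `graph_type`, `node_ids`, the feature matrix `X` in
#' row-major order with its dimensions, and the typed edge list.
#'
#' @param g A `residue_graph` or `atom_graph`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_graph_json <- function(g, path) {
  type <- class(g)[1L]
  obj <- list(
    graph_type = type,
    n_nodes = nrow(g$X),
    n_features = ncol(g$X),
    feature_names = colnames(g$X),
    X = as.numeric(t(g$X)),           # row-major
    edges = if (type == "residue_graph") g$edges else g$bonds
  )
  if (type == "residue_graph") {
    obj$node_ids <- g$node_ids
  } else {
    obj$atoms <- g$atoms
    obj$atom_to_residue <- g$atom_to_residue
  }
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}

#' Read a graph back from JSON
#'
#' @param path File written by [write_graph_json()].
#' @return A `residue_graph` or `atom_graph`, matching what was written.
#' @export
read_graph_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  X <- matrix(obj$X, nrow = obj$n_nodes, ncol = obj$n_features, byrow = TRUE)
  colnames(X) <- obj$feature_names
  edges <- as.data.frame(obj$edges, stringsAsFactors = FALSE)
  if (!nrow(edges)) edges <- new_typed_edges()
  if (obj$graph_type == "residue_graph") {
    structure(list(node_ids = as.data.frame(obj$node_ids), X = X,
                   edges = edges),
              class = "residue_graph")
  } else {
    structure(list(atoms = as.data.frame(obj$atoms), X = X,
                   bonds = edges,
                   atom_to_residue = as.data.frame(obj$atom_to_residue)),
              class = "atom_graph")
  }
}
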