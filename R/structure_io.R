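# Reading protein structures, writing them back out, and assigning
# eight-state secondary structure labels.

#' Construct a protein structure object
#'
#' Low-level constructor used by [read_structure()] and the synthetic
#' structure generator. A `protein_structure` holds a residue table and an
#' atom table; each atom row points at its residue by index.
#'
#' @param id Structure identifier string.
#' @param residues Data frame with columns `chain_id`, `seq_index`, `name3`,
#'   `code1`, `ss8` (one of H,B,E,T,G,I,S,C or NA while unassigned).
#' @param atoms Data frame with columns `res_idx` (row index into `residues`),
#'   `name` (PDB atom name, e.g. "CA"), `element`, `x`, `y`, `z`, `occupancy`.
#' @return An object of class `protein_structure`.
#' @export
protein_structure <- function(id, residues, atoms) {
  stopifnot(is.data.frame(residues), is.data.frame(atoms))
  if (nrow(residues) < 1L) {
    stop("empty structure: no residues", call. = FALSE)
  }
  required <- c("chain_id", "seq_index", "name3", "code1", "ss8")
  if (!all(required %in% names(residues))) {
    stop("residue table missing columns: ",
         paste(setdiff(required, names(residues)), collapse = ", "),
         call. = FALSE)
  }
  areq <- c("res_idx", "name", "element", "x", "y", "z", "occupancy")
  if (!all(areq %in% names(atoms))) {
    stop("atom table missing columns: ",
         paste(setdiff(areq, names(atoms)), collapse = ", "), call. = FALSE)
  }
  if (nrow(atoms) && (min(atoms$res_idx) < 1L ||
                      max(atoms$res_idx) > nrow(residues))) {
    stop("atom res_idx out of range", call. = FALSE)
  }
  bad <- !residues$code1 %in% c(AA_ORDER, "X")
  if (any(bad)) {
    stop("invalid one-letter codes: ",
         paste(unique(residues$code1[bad]), collapse = ", "), call. = FALSE)
  }
  # residues within one chain must be in ascending author numbering
  for (ch in unique(residues$chain_id)) {
    ix <- residues$seq_index[residues$chain_id == ch]
    if (is.unsorted(ix, strictly = FALSE)) {
      stop("residues of chain ", ch, " not in ascending seq_index",
           call. = FALSE)
    }
  }
  structure(
    list(id = id,
         chains = unique(residues$chain_id),
         residues = residues,
         atoms = atoms),
    class = "protein_structure"
  )
}

#' @export
print.protein_structure <- function(x, ...) {
  cat("<protein_structure> ", x$id, "\n",
      "  chains:   ", paste(x$chains, collapse = ", "), "\n",
      "  residues: ", nrow(x$residues), "\n",
      "  atoms:    ", nrow(x$atoms), "\n", sep = "")
  invisible(x)
}

#' Number of residues in a structure
#' @param s A `protein_structure`.
#' @return Integer residue count.
#' @export
n_residues <- function(s) nrow(s$residues)

# Coordinates of one named atom of residue i, or NULL if absent.
atom_xyz <- function(s, i, name) {
  k <- which(s$atoms$res_idx == i & s$atoms$name == name)
  if (!length(k)) return(NULL)
  as.numeric(s$atoms[k[1L], c("x", "y", "z")])
}

# N x 3 matrix of alpha-carbon coordinates (NA rows where CA missing).
ca_matrix <- function(s) {
  n <- n_residues(s)
  m <- matrix(NA_real_, n, 3L)
  ca <- s$atoms[s$atoms$name == "CA", , drop = FALSE]
  m[ca$res_idx, ] <- as.matrix(ca[, c("x", "y", "z")])
  m
}

#' One-letter sequence of a structure
#' @param s A `protein_structure`.
#' @param chain Optional chain id; default all chains concatenated in order.
#' @return Character scalar.
#' @export
structure_sequence <- function(s, chain = NULL) {
  r <- s$residues
  if (!is.null(chain)) r <- r[r$chain_id == chain, , drop = FALSE]
  paste(r$code1, collapse = "")
}

#' Read a protein structure from a PDB file
#'
#' Parses ATOM records of one model, drops waters and hetero ligands,
#' resolves alternate locations by highest occupancy (ties: first record),
#' and keeps only residues with a resolvable alpha carbon. Residues whose
#' three-letter code is not one of the 20 standard amino acids are retained
#' with one-letter code `"X"`.
#'
#' @param path Path to a PDB file.
#' @param model_index Which model to read from multi-model (NMR-style)
#'   files; default the first.
#' @return A [protein_structure()].
#' @export
read_structure <- function(path, model_index = 1L) {
  if (!file.exists(path)) {
    stop("file not found: ", path, call. = FALSE)
  }
  pdb <- tryCatch(
    bio3d::read.pdb(path, multi = model_index > 1L, rm.alt = FALSE,
                    verbose = FALSE),
    error = function(e) stop("PDB parse error in '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  at <- pdb$atom
  if (model_index > 1L) {
    if (is.null(pdb$xyz) || nrow(pdb$xyz) < model_index) {
      stop("model_index ", model_index, " not present in ", path,
           call. = FALSE)
    }
    xyz <- matrix(pdb$xyz[model_index, ], ncol = 3L, byrow = TRUE)
    at$x <- xyz[, 1L]; at$y <- xyz[, 2L]; at$z <- xyz[, 3L]
  }
  at <- at[at$type == "ATOM", , drop = FALSE]
  at <- at[!(at$resid %in% c("HOH", "WAT", "DOD")), , drop = FALSE]
  if (!nrow(at)) {
    stop("empty structure: no ATOM records in ", path, call. = FALSE)
  }
  at$chain[is.na(at$chain)] <- " "
  at$o[is.na(at$o)] <- 1

  # altloc: keep the highest-occupancy copy of each (chain, resno, insert,
  # atom name); ties resolved by file order
  key <- paste(at$chain, at$resno, ifelse(is.na(at$insert), "", at$insert),
               at$elety, sep = "|")
  ord <- order(match(key, unique(key)), -at$o,
               seq_len(nrow(at)), method = "radix")
  at <- at[ord, , drop = FALSE]
  at <- at[!duplicated(paste(at$chain, at$resno,
                             ifelse(is.na(at$insert), "", at$insert),
                             at$elety, sep = "|")), , drop = FALSE]
  at <- at[order(match(paste(at$chain, at$resno, sep = "|"),
                       unique(paste(at$chain, at$resno, sep = "|")))), ,
           drop = FALSE]

  rkey <- paste(at$chain, at$resno, sep = "|")
  rlev <- unique(rkey)
  ridx <- match(rkey, rlev)
  first <- !duplicated(rkey)
  residues <- data.frame(
    chain_id = at$chain[first],
    seq_index = at$resno[first],
    name3 = at$resid[first],
    stringsAsFactors = FALSE
  )
  code1 <- unname(AA_3TO1[residues$name3])
  code1[is.na(code1)] <- "X"
  residues$code1 <- code1
  residues$ss8 <- NA_character_

  elesy <- at$elesy
  if (is.null(elesy)) elesy <- NA_character_
  elesy[is.na(elesy) | elesy == ""] <-
    substr(gsub("[0-9']", "", at$elety[is.na(elesy) | elesy == ""]), 1L, 1L)
  atoms <- data.frame(
    res_idx = ridx,
    name = at$elety,
    element = elesy,
    x = at$x, y = at$y, z = at$z,
    occupancy = at$o,
    stringsAsFactors = FALSE
  )

  # keep only residues with a finite alpha carbon
  has_ca <- vapply(seq_len(nrow(residues)), function(i) {
    xyz <- atom_xyz(list(atoms = atoms), i, "CA")
    !is.null(xyz) && all(is.finite(xyz))
  }, logical(1L))
  if (!any(has_ca)) {
    stop("empty structure: no residues with a resolvable CA in ", path,
         call. = FALSE)
  }
  keep <- which(has_ca)
  atoms <- atoms[atoms$res_idx %in% keep, , drop = FALSE]
  atoms$res_idx <- match(atoms$res_idx, keep)
  residues <- residues[keep, , drop = FALSE]
  rownames(residues) <- rownames(atoms) <- NULL

  protein_structure(
    id = sub("\\.(pdb|ent)$", "", basename(path), ignore.case = TRUE),
    residues = residues, atoms = atoms
  )
}

#' Write a structure to a PDB file
#'
#' @param s A `protein_structure`.
#' @param path Output path.
#' @param bfactor Optional numeric vector of per-residue values written into
#'   the B-factor column of every atom of that residue (default 0).
#' @return `path`, invisibly.
#' @export
write_structure_pdb <- function(s, path, bfactor = NULL) {
  a <- s$atoms
  if (is.null(bfactor)) {
    b <- rep(0, nrow(a))
  } else {
    stopifnot(length(bfactor) == n_residues(s))
    b <- bfactor[a$res_idx]
  }
  bio3d::write.pdb(
    pdb = NULL, file = path,
    xyz = as.numeric(t(as.matrix(a[, c("x", "y", "z")]))),
    resno = s$residues$seq_index[a$res_idx],
    chain = s$residues$chain_id[a$res_idx],
    resid = s$residues$name3[a$res_idx],
    elety = a$name,
    o = a$occupancy,
    b = b
  )
  invisible(path)
}

#' Read a secondary-structure annotation file
#'
#' Two dialects are accepted: classic DSSP output (the columnar block that
#' follows the `#  RESIDUE AA` header line; structure code taken from column
#' 17, blank mapped to C) and a simple two-column whitespace/tab-separated
#' format `chain:resnum  ss8` (lines starting with `#` ignored).
#'
#' @param path Annotation file path.
#' @return Data frame with columns `chain_id`, `seq_index`, `ss8`.
#' @export
read_ss_annotation <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr <- grep("^\\s*#\\s+RESIDUE\\s+AA", lines)
  if (length(hdr)) {
    body <- lines[(hdr[1L] + 1L):length(lines)]
    body <- body[nchar(body) >= 17L]
    resno <- suppressWarnings(as.integer(substr(body, 6L, 10L)))
    chain <- trimws(substr(body, 12L, 12L))
    aa <- substr(body, 14L, 14L)
    keep <- !is.na(resno) & aa != "!"
    ss <- substr(body, 17L, 17L)[keep]
    ss[!ss %in% SS8_STATES] <- "C"
    out <- data.frame(chain_id = chain[keep], seq_index = resno[keep],
                      ss8 = ss, stringsAsFactors = FALSE)
  } else {
    lines <- trimws(lines)
    lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
    parts <- strsplit(lines, "\\s+")
    bad <- vapply(parts, length, 0L) < 2L
    if (any(bad)) stop("malformed annotation line: ", lines[bad][1L],
                       call. = FALSE)
    key <- vapply(parts, `[`, "", 1L)
    kk <- strsplit(key, ":", fixed = TRUE)
    if (any(vapply(kk, length, 0L) != 2L)) {
      stop("annotation keys must look like chain:resnum", call. = FALSE)
    }
    ss <- toupper(vapply(parts, `[`, "", 2L))
    ss[ss == "-"] <- "C"
    if (!all(ss %in% SS8_STATES)) {
      stop("unknown ss8 state(s): ",
           paste(unique(ss[!ss %in% SS8_STATES]), collapse = ", "),
           call. = FALSE)
    }
    out <- data.frame(
      chain_id = vapply(kk, `[`, "", 1L),
      seq_index = as.integer(vapply(kk, `[`, "", 2L)),
      ss8 = ss, stringsAsFactors = FALSE
    )
  }
  out
}

#' Assign secondary structure labels
#'
#' With an external annotation (DSSP output or two-column TSV, see
#' [read_ss_annotation()]), labels are copied verbatim onto matching
#' residues (`-` mapped to C). Without one, a geometry fallback assigns a
#' three-state subset from the alpha-carbon trace: a residue is helical (H)
#' when it lies in a run of four consecutive CA(i)-CA(i+3) distances within
#' [4.5, 6.5] angstrom; extended (E) when the CA(i-1)-CA(i+1) spans around
#' it all exceed 6.0 angstrom; otherwise coil (C). The fallback never emits
#' the remaining five states; the one-hot encoding keeps their slots.
#'
#' @param s A `protein_structure`.
#' @param external Optional annotation file path or a data frame as returned
#'   by [read_ss_annotation()].
#' @return The structure with `ss8` filled for every residue.
#' @export
assign_secondary_structure <- function(s, external = NULL) {
  stopifnot(inherits(s, "protein_structure"))
  if (!is.null(external)) {
    ann <- if (is.character(external)) read_ss_annotation(external) else external
    key <- paste(ann$chain_id, ann$seq_index, sep = ":")
    skey <- paste(s$residues$chain_id, s$residues$seq_index, sep = ":")
    unknown <- setdiff(key, skey)
    if (length(unknown)) {
      stop("annotation refers to residues not in the structure: ",
           paste(utils::head(unknown, 5L), collapse = ", "), call. = FALSE)
    }
    m <- match(skey, key)
    if (anyNA(m)) {
      stop("annotation missing for residues: ",
           paste(utils::head(skey[is.na(m)], 5L), collapse = ", "),
           call. = FALSE)
    }
    s$residues$ss8 <- ann$ss8[m]
    return(s)
  }

  ca <- ca_matrix(s)
  n <- nrow(ca)
  ss <- rep("C", n)
  d <- function(i, j) sqrt(sum((ca[i, ] - ca[j, ])^2))
  # per-chain windows (no labels across chain breaks)
  for (ch in s$chains) {
    idx <- which(s$residues$chain_id == ch)
    m <- length(idx)
    if (m < 4L) next
    d13 <- vapply(seq_len(m - 3L), function(k) d(idx[k], idx[k + 3L]),
                  numeric(1L))
    helical_win <- d13 >= 4.5 & d13 <= 6.5
    if (m >= 7L) {
      for (st in seq_len(m - 6L)) {
        if (all(helical_win[st:(st + 3L)])) {
          ss[idx[st:(st + 6L)]] <- "H"
        }
      }
    }
    if (m >= 5L) {
      for (k in 3L:(m - 2L)) {
        if (ss[idx[k]] == "H") next
        if (d(idx[k - 2L], idx[k]) > 6.0 &&
            d(idx[k - 1L], idx[k + 1L]) > 6.0 &&
            d(idx[k], idx[k + 2L]) > 6.0) {
          ss[idx[k]] <- "E"
        }
      }
    }
  }
  s$residues$ss8 <- ss
  s
}
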