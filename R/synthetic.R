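# Seed-deterministic synthetic fixtures: ideal helical structures with
# enough pseudo-atoms to exercise every edge detector, and affinity
# datasets generated from a planted, recoverable binding rule.

#' Planted binding rule
#'
#' Describes the ground-truth signal injected into synthetic affinity
#' data: peptides carrying one of the favored residues at the anchor
#' position gain `effect_size` on the transformed affinity scale, on top
#' of a baseline of 0.3, with Gaussian noise. The default rule anchors at
#' peptide position 1 with large hydrophobic residues favored, mirroring
#' the P1-pocket preference of class II HLA grooves; position 1 also keeps
#' the positional cue (the free N-terminal amine) within a few bond hops
#' of the anchor side chain, so the rule is recoverable from atom-level
#' graphs by construction.
#'
#' @param anchor_position 1-based peptide position carrying the signal.
#' @param favored_residues One-letter codes that activate the effect.
#' @param pocket_residue_index Structure node index recorded as the causal
#'   pocket residue in the ground truth (used by the structure-side rule
#'   variant).
#' @param effect_size Score-scale effect, > 0 (default 0.4).
#' @param noise_sd Gaussian noise standard deviation on the score scale.
#' @param base Baseline transformed score (default 0.3).
#' @param mode `"peptide_anchor"` (default) or `"structure_pocket"` (the
#'   provided structure-side variant, where the effect is keyed to the
#'   pocket residue of a per-pair structure).
#' @param seed Integer seed.
#' @return A `planted_rule` list.
#' @export
planted_rule <- function(anchor_position = 1L,
                         favored_residues = c("F", "W", "Y", "L", "I", "V"),
                         pocket_residue_index = 15L,
                         effect_size = 0.4,
                         noise_sd = 0.05,
                         base = 0.3,
                         mode = c("peptide_anchor", "structure_pocket"),
                         seed = 1L) {
  stopifnot(effect_size > 0, noise_sd >= 0, anchor_position >= 1L)
  mode <- match.arg(mode)
  structure(list(anchor_position = as.integer(anchor_position),
                 favored_residues = favored_residues,
                 pocket_residue_index = as.integer(pocket_residue_index),
                 effect_size = effect_size, noise_sd = noise_sd,
                 base = base, mode = mode, seed = as.integer(seed)),
            class = "planted_rule")
}

#' Generate an ideal helical structure
#'
#' Builds an alpha-helical CA trace (radius 2.3 A, rise 1.5 A per residue,
#' 100 degrees per residue; consecutive CA-CA distance about 3.83 A) with
#' synthesized backbone N, C and carbonyl O positions placed on the same
#' helix so that every C(i)-N(i+1) peptide bond falls inside the detector
#' cutoff, plus a CB pseudo-atom for every non-glycine residue. On
#' request, pairs of residues are rewritten to cysteine with SG atoms
#' placed 2.04 A apart (disulfide range), or to lysine/glutamate with
#' NZ/OE1 placed 3.5 A apart (ionic range).
#'
#' @param n_res Number of residues (at least 5).
#' @param seq Optional one-letter sequence of length `n_res`; random under
#'   `seed` when omitted.
#' @param seed Seed for the random sequence.
#' @param disulfide_pairs List of index pairs engineered into CYS-CYS
#'   bridges.
#' @param ionic_pairs List of index pairs engineered into LYS-GLU salt
#'   bridges.
#' @param chain_id Chain identifier (default "A").
#' @param id Structure identifier.
#' @return A [protein_structure()].
#' @export
gen_helix_structure <- function(n_res, seq = NULL, seed = 1L,
                                disulfide_pairs = NULL, ionic_pairs = NULL,
                                chain_id = "A", id = "synthetic_helix") {
  if (n_res < 5L) stop("helix fixture needs at least 5 residues",
                       call. = FALSE)
  if (is.null(seq)) {
    set.seed(seed)
    seq <- paste(sample(AA_ORDER, n_res, replace = TRUE), collapse = "")
  }
  aa <- strsplit(seq, "")[[1L]]
  if (length(aa) != n_res) stop("seq length must equal n_res", call. = FALSE)
  for (p in disulfide_pairs) aa[p] <- "C"
  for (p in ionic_pairs) { aa[p[1L]] <- "K"; aa[p[2L]] <- "E" }

  radius <- 2.3; rise <- 1.5; twist <- 100 * pi / 180
  helix_point <- function(i, dfrac, r = radius) {
    th <- (i - 1 + dfrac) * twist
    c(r * cos(th), r * sin(th), (i - 1 + dfrac) * rise)
  }
  radial_out <- function(i, dfrac, extra) {
    th <- (i - 1 + dfrac) * twist
    c(cos(th), sin(th), 0) * extra
  }

  atoms <- list()
  add_atom <- function(res, name, elem, xyz) {
    atoms[[length(atoms) + 1L]] <<- data.frame(
      res_idx = res, name = name, element = elem,
      x = xyz[1L], y = xyz[2L], z = xyz[3L], occupancy = 1,
      stringsAsFactors = FALSE)
  }
  for (i in seq_len(n_res)) {
    add_atom(i, "N", "N", helix_point(i, -0.35))
    ca <- helix_point(i, 0)
    add_atom(i, "CA", "C", ca)
    cc <- helix_point(i, 0.35)
    add_atom(i, "C", "C", cc)
    add_atom(i, "O", "O", cc + radial_out(i, 0.35, 1.23))
    if (aa[i] != "G") {
      add_atom(i, "CB", "C", ca + radial_out(i, 0, 1.53))
    }
  }
  atoms <- do.call(rbind, atoms)

  place_pair <- function(i, j, name_i, name_j, elem_i, elem_j, gap) {
    cbi <- helix_point(i, 0) + radial_out(i, 0, 1.53)
    cbj <- helix_point(j, 0) + radial_out(j, 0, 1.53)
    u <- (cbj - cbi); u <- u / sqrt(sum(u^2))
    m <- (cbi + cbj) / 2
    rbind(
      data.frame(res_idx = i, name = name_i, element = elem_i,
                 x = m[1L] - u[1L] * gap / 2, y = m[2L] - u[2L] * gap / 2,
                 z = m[3L] - u[3L] * gap / 2, occupancy = 1,
                 stringsAsFactors = FALSE),
      data.frame(res_idx = j, name = name_j, element = elem_j,
                 x = m[1L] + u[1L] * gap / 2, y = m[2L] + u[2L] * gap / 2,
                 z = m[3L] + u[3L] * gap / 2, occupancy = 1,
                 stringsAsFactors = FALSE))
  }
  for (p in disulfide_pairs) {
    atoms <- rbind(atoms, place_pair(p[1L], p[2L], "SG", "SG", "S", "S",
                                     2.04))
  }
  for (p in ionic_pairs) {
    atoms <- rbind(atoms, place_pair(p[1L], p[2L], "NZ", "OE1", "N", "O",
                                     3.5))
  }
  atoms <- atoms[order(atoms$res_idx), , drop = FALSE]
  rownames(atoms) <- NULL

  residues <- data.frame(
    chain_id = chain_id,
    seq_index = seq_len(n_res),
    name3 = unname(AA_1TO3[aa]),
    code1 = aa,
    ss8 = NA_character_,
    stringsAsFactors = FALSE
  )
  protein_structure(id = id, residues = residues, atoms = atoms)
}

#' Generate a planted-rule affinity dataset
#'
#' Draws peptides uniformly over the 20 residues and assigns each pair a
#' transformed score `base + effect_size * [anchor residue favored] +
#' N(0, noise_sd)`, clamped to `[0, 1]`; the stored IC50 is the exact
#' inverse transform of that score. Ground truth (the causal peptide
#' position, favored set, and pocket node) travels with the dataset.
#' Generation is fully determined by `rule$seed`; identical seeds give
#' byte-identical datasets.
#'
#' @param n_pairs Number of HLA-peptide pairs (at least 10; default 200).
#' @param rule A [planted_rule()].
#' @param peptide_len Peptide length (default 9).
#' @param hla_id Identifier recorded for the fixture HLA (default
#'   "HLAFIX01").
#' @return A `planted_dataset` list: `records` (data frame `hla_id`,
#'   `peptide_seq`, `ic50_nM`), `scores` (the noiseless-inverse-consistent
#'   transformed scores), `truth` (rule and per-pair favored indicator).
#' @export
gen_affinity_dataset <- function(n_pairs = 200L, rule = planted_rule(),
                                 peptide_len = 9L, hla_id = "HLAFIX01") {
  stopifnot(inherits(rule, "planted_rule"))
  if (n_pairs < 10L) stop("need at least 10 pairs", call. = FALSE)
  if (rule$anchor_position > peptide_len) {
    stop("anchor_position exceeds peptide length", call. = FALSE)
  }
  set.seed(rule$seed)
  peps <- vapply(seq_len(n_pairs), function(i) {
    paste(sample(AA_ORDER, peptide_len, replace = TRUE), collapse = "")
  }, character(1L))
  anchor <- substr(peps, rule$anchor_position, rule$anchor_position)
  favored <- anchor %in% rule$favored_residues
  score <- rule$base + rule$effect_size * favored +
    stats::rnorm(n_pairs, sd = rule$noise_sd)
  score <- pmin(1, pmax(0, score))
  # keep scores strictly inside (0, 1] so the IC50 inverse stays exact
  score <- pmax(score, 1e-6)
  records <- data.frame(
    hla_id = hla_id,
    peptide_seq = peps,
    ic50_nM = score_to_ic50(score),
    stringsAsFactors = FALSE
  )
  structure(list(
    records = records,
    scores = score,
    truth = list(anchor_position = rule$anchor_position,
                 favored_residues = rule$favored_residues,
                 pocket_residue_index = rule$pocket_residue_index,
                 favored = favored),
    rule = rule
  ), class = "planted_dataset")
}

#' Write a training table
#'
#' Tab-separated dialect consumed by the training tools: columns
#' `hla_id`, `structure_path`, `peptide_seq`, `ic50_nM` (or `score`).
#'
#' @param records Data frame of affinity records.
#' @param path Output TSV path.
#' @param structure_path Structure file path recorded for each HLA id
#'   (scalar or named by `hla_id`).
#' @return `path`, invisibly.
#' @export
write_affinity_table <- function(records, path, structure_path = "") {
  df <- records
  if (!"structure_path" %in% names(df)) {
    sp <- if (length(structure_path) > 1L) {
      unname(structure_path[df$hla_id])
    } else {
      structure_path
    }
    df$structure_path <- sp
  }
  front <- c("hla_id", "structure_path", "peptide_seq")
  df <- df[, c(front, setdiff(names(df), front)), drop = FALSE]
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a training table
#'
#' @param path TSV written by [write_affinity_table()] (columns `hla_id`,
#'   `structure_path`, `peptide_seq`, and `ic50_nM` or `score`).
#' @return Data frame of affinity records.
#' @export
read_affinity_table <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  need <- c("hla_id", "peptide_seq")
  if (!all(need %in% names(df))) {
    stop("training table must have columns hla_id, peptide_seq and ",
         "ic50_nM or score", call. = FALSE)
  }
  if (!any(c("ic50_nM", "score") %in% names(df))) {
    stop("training table needs an ic50_nM or score column", call. = FALSE)
  }
  df
}

#' Write a complete fixture set to a directory
#'
#' Emits the helix PDB, a FASTA of the peptides, the training TSV, and a
#' JSON record of the planted ground truth.
#'
#' @param dir Output directory (created if missing).
#' @param seed Master seed driving both the structure and the dataset.
#' @param n_pairs,peptide_len,n_res Fixture sizes.
#' @param rule Optional [planted_rule()]; default uses `seed`.
#' @return Invisibly, a list of the written paths.
#' @export
write_fixture_set <- function(dir, seed = 1L, n_pairs = 200L,
                              peptide_len = 9L, n_res = 30L, rule = NULL) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  if (is.null(rule)) rule <- planted_rule(seed = seed)
  s <- gen_helix_structure(n_res, seed = seed)
  ds <- gen_affinity_dataset(n_pairs, rule, peptide_len)
  pdb <- file.path(dir, "hla_fixture.pdb")
  write_structure_pdb(s, pdb)
  fasta <- file.path(dir, "peptides.fasta")
  writeLines(paste0(">pep", seq_len(n_pairs), "\n", ds$records$peptide_seq),
             fasta)
  tsv <- file.path(dir, "train.tsv")
  write_affinity_table(ds$records, tsv, structure_path = pdb)
  truth <- file.path(dir, "truth.json")
  jsonlite::write_json(ds$truth, truth, auto_unbox = TRUE, digits = NA)
  invisible(list(pdb = pdb, fasta = fasta, tsv = tsv, truth = truth))
}
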