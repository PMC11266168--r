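# Mutation scan: extract the 9-mer windows around a substitution, score
# wild-type versus mutant peptides across an HLA panel, and test the
# paired affinity change.

#' Describe a single amino-acid substitution
#'
#' @param protein_seq One-letter protein sequence.
#' @param position 1-based position of the substitution.
#' @param ref_aa Reference residue (must match `protein_seq` at
#'   `position`).
#' @param alt_aa Alternate residue (must differ from `ref_aa`).
#' @return A `substitution_event`.
#' @export
substitution_event <- function(protein_seq, position, ref_aa, alt_aa) {
  stopifnot(is.character(protein_seq), length(protein_seq) == 1L)
  n <- nchar(protein_seq)
  if (position < 1L || position > n) {
    stop("position ", position, " outside protein of length ", n,
         call. = FALSE)
  }
  have <- substr(protein_seq, position, position)
  if (have != ref_aa) {
    stop("reference mismatch at position ", position, ": protein has '",
         have, "', event says '", ref_aa, "'", call. = FALSE)
  }
  if (alt_aa == ref_aa) stop("alt_aa must differ from ref_aa",
                             call. = FALSE)
  if (!alt_aa %in% AA_ORDER) stop("unsupported alternate residue '",
                                  alt_aa, "'", call. = FALSE)
  structure(list(protein_seq = protein_seq, position = as.integer(position),
                 ref_aa = ref_aa, alt_aa = alt_aa),
            class = "substitution_event")
}

#' Extract the 9-mer windows covering a substitution
#'
#' Returns every 9-mer window of the protein that contains the substituted
#' position (up to nine windows; fewer near the sequence ends), paired
#' with the corresponding mutant window, which differs from the wild type
#' at exactly one aligned position.
#'
#' @param ev A [substitution_event()].
#' @return Data frame with columns `start`, `offset` (position of the
#'   substitution within the window), `wt`, `mut`.
#' @export
extract_9mers <- function(ev) {
  stopifnot(inherits(ev, "substitution_event"))
  L <- nchar(ev$protein_seq)
  if (L < 9L) {
    stop("protein too short for 9-mer extraction (length ", L, ")",
         call. = FALSE)
  }
  starts <- max(1L, ev$position - 8L):min(ev$position, L - 8L)
  wt <- vapply(starts, function(s) substr(ev$protein_seq, s, s + 8L),
               character(1L))
  mutseq <- ev$protein_seq
  substr(mutseq, ev$position, ev$position) <- ev$alt_aa
  mut <- vapply(starts, function(s) substr(mutseq, s, s + 8L),
                character(1L))
  data.frame(start = starts, offset = ev$position - starts + 1L,
             wt = wt, mut = mut, stringsAsFactors = FALSE)
}

#' Affinity change of a substitution across an HLA panel
#'
#' For every HLA in the panel, all wild-type and mutant 9-mer windows are
#' scored and combined (per-HLA maximum by default, the usual epitope-scan
#' convention; `"mean"` available); the per-HLA deltas
#' `score_mut - score_wt` are then compared with a two-sided paired
#' t-test. A synonymous control (identical windows) yields all-zero deltas
#' and an undefined test, flagged rather than failed.
#'
#' @param model A trained `affinity_model`.
#' @param panel Named list of `residue_graph` objects (the HLA panel).
#' @param ev A [substitution_event()].
#' @param combine `"max"` (default) or `"mean"` over windows.
#' @return A `delta_affinity_result`: `per_hla` data frame (`hla_id`,
#'   `score_wt`, `score_mut`, `delta`), `t_statistic`, `p_value`,
#'   `degenerate` flag.
#' @export
delta_affinity <- function(model, panel, ev, combine = c("max", "mean")) {
  combine <- match.arg(combine)
  stopifnot(inherits(model, "affinity_model"), length(panel) >= 1L)
  if (length(panel) < 2L) {
    stop("paired t-test undefined for panel size < 2", call. = FALSE)
  }
  win <- extract_9mers(ev)
  seqs <- unique(c(win$wt, win$mut))
  graphs <- lapply(seqs, function(s) suppressWarnings(build_peptide_graph(s)))
  names(graphs) <- seqs
  agg <- function(v) if (combine == "max") max(v) else mean(v)
  ids <- if (is.null(names(panel))) paste0("hla", seq_along(panel)) else
    names(panel)
  rows <- lapply(seq_along(panel), function(k) {
    swt <- agg(vapply(win$wt, function(s)
      predict_affinity(model, panel[[k]], graphs[[s]]), numeric(1L)))
    smu <- agg(vapply(win$mut, function(s)
      predict_affinity(model, panel[[k]], graphs[[s]]), numeric(1L)))
    data.frame(hla_id = ids[k], score_wt = swt, score_mut = smu,
               delta = smu - swt, stringsAsFactors = FALSE)
  })
  per_hla <- do.call(rbind, rows)
  degenerate <- stats::sd(per_hla$delta) < .Machine$double.eps
  if (degenerate) {
    t_stat <- NA_real_; p_val <- NA_real_
    warning("all per-HLA deltas identical; paired t-test undefined",
            call. = FALSE)
  } else {
    tt <- stats::t.test(per_hla$score_mut, per_hla$score_wt,
                        paired = TRUE, alternative = "two.sided")
    t_stat <- unname(tt$statistic); p_val <- tt$p.value
  }
  structure(list(per_hla = per_hla, t_statistic = t_stat,
                 p_value = p_val, degenerate = degenerate,
                 event = ev, combine = combine),
            class = "delta_affinity_result")
}

#' @export
print.delta_affinity_result <- function(x, ...) {
  cat("<delta_affinity_result> ", x$event$ref_aa, x$event$position,
      x$event$alt_aa, " over ", nrow(x$per_hla), " HLAs\n",
      "  mean delta = ", signif(mean(x$per_hla$delta), 4L),
      ", t = ", signif(x$t_statistic, 4L),
      ", p = ", signif(x$p_value, 4L), "\n", sep = "")
  invisible(x)
}

#' Read a substitution table
#'
#' TSV with columns `protein_id`, `position`, `ref`, `alt`.
#'
#' @param path Input path.
#' @return Data frame.
#' @export
read_substitution_table <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  need <- c("protein_id", "position", "ref", "alt")
  if (!all(need %in% names(df))) {
    stop("substitution table needs columns ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  df
}

#' Write per-HLA mutation-scan results to CSV
#'
#' @param res A `delta_affinity_result`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_delta_affinity_csv <- function(res, path) {
  df <- res$per_hla
  df$t_statistic <- res$t_statistic
  df$p_value <- res$p_value
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
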