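# Gradient-weighted activation mapping over the last GCN layer of either
# branch, an occlusion oracle, and structure annotation for visualization.

#' Capture the last-layer feature map and its partial derivatives
#'
#' Runs an evaluation-mode forward pass and records `T`, the node x channel
#' activation matrix of the last GCN layer of the requested branch,
#' together with the exact first partials `grad1 = dP/dT` (reverse-mode
#' chain rule through the readout and MLP head, on the raw unclamped
#' prediction) and the diagonal second partials `grad2 = d2P/dT2`. The
#' prediction head downstream of `T` (mean/sum/max pooling, linear maps and
#' ReLU) is piecewise linear, so every term of the exact diagonal Hessian
#' carries a ReLU second derivative and vanishes almost everywhere; `grad2`
#' is therefore exactly zero wherever the derivative exists.
#'
#' @param model An `affinity_model` (evaluation mode is implied).
#' @param hla A `residue_graph`.
#' @param pep An `atom_graph`.
#' @param branch `"hla"` or `"peptide"`.
#' @return A `feature_map`: `T`, `grad1`, `grad2` (same shape), the raw
#'   prediction `P`, the pooled vector of the other branch, and node
#'   identifiers.
#' @export
capture_feature_map <- function(model, hla, pep,
                                branch = c("hla", "peptide")) {
  branch <- match.arg(branch)
  stopifnot(inherits(model, "affinity_model"))
  Ws <- if (branch == "hla") model$hla_W else model$pep_W
  if (!length(Ws)) {
    stop("branch '", branch, "' has no GCN layers", call. = FALSE)
  }
  ht <- prepare_graph(model, hla, "hla")
  pt <- prepare_graph(model, pep, "pep")
  fw <- pair_forward(model, ht, pt, training = FALSE)
  bc <- if (branch == "hla") fw$hla else fw$pep
  other_h <- if (branch == "hla") fw$pep$h else fw$hla$h

  mb <- mlp_backward(model$mlp, fw$mlp, dP = 1)
  Ch <- length(fw$hla$h)
  dvec <- if (branch == "hla") {
    mb$dz0[seq_len(Ch)]
  } else {
    mb$dz0[(Ch + 1L):length(mb$dz0)]
  }
  grad1 <- readout_backward(dvec, bc, model$config$readout)
  # exact diagonal second partials: zero for the piecewise-linear head
  grad2 <- readout_backward(mlp_diag_hessian(model$mlp, fw$mlp,
                                             branch, Ch),
                            bc, model$config$readout) * 0

  node_ids <- if (branch == "hla") {
    paste(hla$node_ids$chain_id, hla$node_ids$seq_index, sep = ":")
  } else {
    if (!is.null(pep$atom_to_residue)) {
      paste0("atom", seq_len(nrow(pep$X)), "/",
             pep$atom_to_residue$code, pep$atom_to_residue$position)
    } else {
      paste0("atom", seq_len(nrow(pep$X)))
    }
  }
  structure(list(T = bc$T, grad1 = grad1, grad2 = grad2,
                 P = fw$P, other_h = other_h, branch = branch,
                 readout = model$config$readout, node_ids = node_ids),
            class = "feature_map")
}

# Diagonal Hessian of the raw prediction with respect to the pooled vector
# of one branch. Every second-order term of the ReLU MLP is of the form
# (path weight)^2 * relu''(a) with relu'' = 0 almost everywhere, so the
# exact value is the zero vector (the chain rule collapses term by term).
mlp_diag_hessian <- function(mlp, cache, branch, Ch) {
  len <- if (branch == "hla") Ch else length(cache$z0) - Ch
  numeric(len)
}

#' Re-evaluate the prediction from a modified feature map
#'
#' Recomputes the raw prediction with the captured branch's last-layer
#' activations replaced by `T_new`, holding the other branch fixed. This is
#' the forward map that the partial derivatives of
#' [capture_feature_map()] differentiate; finite differences of it provide
#' an independent check of those gradients.
#'
#' @param model The `affinity_model` used for the capture.
#' @param fm A `feature_map`.
#' @param T_new Replacement activation matrix (same shape as `fm$T`).
#' @return Raw (unclamped) prediction.
#' @export
predict_from_feature_map <- function(model, fm, T_new) {
  stopifnot(identical(dim(T_new), dim(fm$T)))
  h <- graph_readout(T_new, fm$readout)
  z0 <- if (fm$branch == "hla") c(h, fm$other_h) else c(fm$other_h, h)
  mlp_forward(model$mlp, z0, dropout = 0, training = FALSE)$P
}

#' Grad-CAM-style channel weighting coefficients
#'
#' Elementwise `alpha = grad1 / (grad1 + T * grad2)`. Where the denominator
#' magnitude falls below `eps` (including the 0/0 case of a vanishing first
#' partial), `alpha` is set to 1, so the method degrades to plain
#' rectified-gradient weighting instead of producing non-finite values.
#' With a purely linear head (`grad2 = 0`, `grad1 != 0`) the coefficients
#' are identically 1.
#'
#' @param fm A `feature_map` from [capture_feature_map()].
#' @param eps Degeneracy guard on the denominator (default 1e-12).
#' @return Matrix of coefficients, same shape as `fm$T`.
#' @export
alpha_coefficients <- function(fm, eps = 1e-12) {
  stopifnot(inherits(fm, "feature_map"))
  denom <- fm$grad1 + fm$T * fm$grad2
  alpha <- fm$grad1 / denom
  alpha[abs(denom) < eps] <- 1
  alpha
}

#' Gradient-weighted activation scores for graph nodes
#'
#' Channel weights are the alpha-weighted sums of the rectified first
#' partials, `w_c = sum_i alpha_ic * ReLU(grad1_ic)`; each node's raw score
#' is the rectified weighted activation `s_i = ReLU(sum_c w_c * T_ic)`; the
#' scalar `omega = sum_c w_c` is reported as a diagnostic. Raw scores are
#' min-max normalized to `[0, 1]` per graph for the blue-to-red display
#' scale; if all raw scores coincide the normalized scores are defined as
#' all zeros, with a warning.
#'
#' @inheritParams capture_feature_map
#' @param eps Degeneracy guard passed to [alpha_coefficients()].
#' @return An `attribution_result`: `node_ids`, `raw`, `normalized`,
#'   `omega`, `branch`.
#' @export
gradwam_scores <- function(model, hla, pep, branch = c("hla", "peptide"),
                           eps = 1e-12) {
  branch <- match.arg(branch)
  fm <- capture_feature_map(model, hla, pep, branch)
  alpha <- alpha_coefficients(fm, eps)
  w <- colSums(alpha * pmax(fm$grad1, 0))
  raw <- as.numeric(pmax(fm$T %*% w, 0))
  rng <- range(raw)
  if (rng[2L] - rng[1L] < .Machine$double.eps) {
    warning("all node scores equal; normalized scores set to 0",
            call. = FALSE)
    normalized <- rep(0, length(raw))
  } else {
    normalized <- (raw - rng[1L]) / (rng[2L] - rng[1L])
  }
  structure(list(node_ids = fm$node_ids, raw = raw,
                 normalized = normalized, omega = sum(w), branch = branch),
            class = "attribution_result")
}

#' @export
print.attribution_result <- function(x, ...) {
  top <- order(x$raw, decreasing = TRUE)[seq_len(min(5L, length(x$raw)))]
  cat("<attribution_result> ", x$branch, " branch, ", length(x$raw),
      " nodes, omega = ", signif(x$omega, 4L), "\n  top nodes: ",
      paste(x$node_ids[top], collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Occlusion importance scores
#'
#' Independent attribution oracle: for each node of the chosen branch, its
#' feature row is zeroed, the pair is re-scored, and
#' `delta = P_full - P_occluded` is recorded on the raw prediction scale.
#'
#' The default occludes rows of the last-layer feature map `T` -- the same
#' object the gradient attribution scores -- so the oracle and the method
#' measure importance at the same interface. `level = "input"` instead
#' zeroes the node's standardized input features and re-runs the whole
#' branch; that variant also counts the indirect influence a node exerts
#' on its neighbours' embeddings through the convolution, so it answers a
#' related but broader question.
#'
#' @inheritParams capture_feature_map
#' @param level `"feature_map"` (default) or `"input"`.
#' @return Numeric vector of per-node prediction drops.
#' @export
occlusion_scores <- function(model, hla, pep,
                             branch = c("hla", "peptide"),
                             level = c("feature_map", "input")) {
  branch <- match.arg(branch)
  level <- match.arg(level)
  stopifnot(inherits(model, "affinity_model"))
  if (level == "feature_map") {
    fm <- capture_feature_map(model, hla, pep, branch)
    return(vapply(seq_len(nrow(fm$T)), function(i) {
      Tmod <- fm$T
      Tmod[i, ] <- 0
      fm$P - predict_from_feature_map(model, fm, Tmod)
    }, numeric(1L)))
  }
  ht <- prepare_graph(model, hla, "hla")
  pt <- prepare_graph(model, pep, "pep")
  P_full <- pair_forward(model, ht, pt, training = FALSE)$P
  tens <- if (branch == "hla") ht else pt
  n <- nrow(tens$X)
  vapply(seq_len(n), function(i) {
    tmod <- tens
    tmod$X[i, ] <- 0
    tmod$M1 <- tmod$Abar %*% tmod$X
    P_occ <- if (branch == "hla") {
      pair_forward(model, tmod, pt, training = FALSE)$P
    } else {
      pair_forward(model, ht, tmod, training = FALSE)$P
    }
    P_full - P_occ
  }, numeric(1L))
}

#' Aggregate peptide-atom attribution to residue positions
#'
#' @param attr An `attribution_result` from the peptide branch.
#' @param pep The `atom_graph` it was computed on (needs
#'   `atom_to_residue`).
#' @param fun Aggregation over the atoms of one residue (default `max`).
#' @return Data frame with `position`, `code`, `raw`, `normalized`.
#' @export
attribution_by_residue <- function(attr, pep, fun = max) {
  stopifnot(inherits(attr, "attribution_result"),
            !is.null(pep$atom_to_residue))
  map <- pep$atom_to_residue
  pos <- sort(unique(map$position))
  raw <- vapply(pos, function(p) fun(attr$raw[map$position == p]),
                numeric(1L))
  nrm <- vapply(pos, function(p) fun(attr$normalized[map$position == p]),
                numeric(1L))
  data.frame(position = pos,
             code = map$code[match(pos, map$position)],
             raw = raw, normalized = nrm, stringsAsFactors = FALSE)
}

#' Write attribution scores to CSV
#'
#' Columns: `node_id`, `chain`, `resnum` (HLA branch) or `atom`
#' (peptide branch), `raw`, `normalized`.
#'
#' @param attr An `attribution_result`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_attribution_csv <- function(attr, path) {
  df <- data.frame(node_id = attr$node_ids, raw = attr$raw,
                   normalized = attr$normalized, stringsAsFactors = FALSE)
  if (attr$branch == "hla") {
    parts <- strsplit(attr$node_ids, ":", fixed = TRUE)
    df$chain <- vapply(parts, `[`, "", 1L)
    df$resnum <- as.integer(vapply(parts, `[`, "", 2L))
    df <- df[, c("node_id", "chain", "resnum", "raw", "normalized")]
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Annotate a structure with attribution scores
#'
#' Writes a PDB in which every atom's B-factor carries 100 x the residue's
#' normalized score (so any molecular viewer renders the blue-to-red
#' importance scale); residues without a score get 0.00.
#'
#' @param s The `protein_structure` the scores refer to.
#' @param attr An `attribution_result` from the HLA branch whose node ids
#'   (`chain:resnum`) all occur in `s`.
#' @param path Output PDB path.
#' @return `path`, invisibly.
#' @export
annotate_structure <- function(s, attr, path) {
  stopifnot(inherits(s, "protein_structure"),
            inherits(attr, "attribution_result"))
  skey <- paste(s$residues$chain_id, s$residues$seq_index, sep = ":")
  miss <- setdiff(attr$node_ids, skey)
  if (length(miss)) {
    stop("attribution refers to residues not in the structure: ",
         paste(utils::head(miss, 5L), collapse = ", "), call. = FALSE)
  }
  b <- rep(0, n_residues(s))
  b[match(attr$node_ids, skey)] <- 100 * attr$normalized
  write_structure_pdb(s, path, bfactor = b)
  invisible(path)
}
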