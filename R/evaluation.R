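# Binder/nonbinder classification metrics, ROC/AUC, and the k-fold
# cross-validation protocol.

#' Confusion counts at the binder cutoff
#'
#' Both predicted and true scores are binarized at the cutoff (strictly
#' greater = positive) and tallied into TP/TN/FP/FN.
#'
#' @param pred_scores,true_scores Equal-length numeric vectors.
#' @param cutoff Binarization threshold (default [binder_cutoff_score()]).
#' @return A `confusion_counts` list with fields `TP`, `TN`, `FP`, `FN`.
#' @export
confusion_counts <- function(pred_scores, true_scores,
                             cutoff = binder_cutoff_score()) {
  if (length(pred_scores) != length(true_scores)) {
    stop("prediction and truth lengths differ", call. = FALSE)
  }
  if (!length(pred_scores)) stop("empty score vectors", call. = FALSE)
  p <- pred_scores > cutoff
  t <- true_scores > cutoff
  structure(list(TP = sum(p & t), TN = sum(!p & !t),
                 FP = sum(p & !t), FN = sum(!p & t)),
            class = "confusion_counts")
}

#' Classification metrics from confusion counts
#'
#' Accuracy `(TP+TN)/total`, sensitivity `TP/(TP+FN)`, specificity
#' `TN/(TN+FP)` and the Matthews correlation coefficient
#' `(TN*TP - FN*FP) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`. A metric whose
#' denominator is zero is reported as `NA` (undefined), never as 0.
#'
#' @param c A `confusion_counts` object or a list with fields TP, TN, FP,
#'   FN.
#' @return Named numeric vector `Acc`, `Sn`, `Sp`, `MCC`.
#' @export
classification_metrics <- function(c) {
  TP <- c$TP; TN <- c$TN; FP <- c$FP; FN <- c$FN
  total <- TP + TN + FP + FN
  if (total < 1L) stop("empty confusion table", call. = FALSE)
  acc <- (TP + TN) / total
  sn <- if ((TP + FN) > 0) TP / (TP + FN) else NA_real_
  sp <- if ((TN + FP) > 0) TN / (TN + FP) else NA_real_
  denom2 <- prod(c(TP + FP, TP + FN, TN + FP, TN + FN))
  mcc <- if (denom2 > 0) (TN * TP - FN * FP) / sqrt(denom2) else NA_real_
  c(Acc = acc, Sn = sn, Sp = sp, MCC = mcc)
}

#' Area under the ROC curve
#'
#' Rank-based (equivalently trapezoid) AUC with midranks for ties: the
#' probability that a random positive scores above a random negative,
#' counting ties as one half.
#'
#' @param pred_scores Numeric prediction scores.
#' @param true_labels Logical or 0/1 labels; both classes must be present.
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(pred_scores, true_labels) {
  lab <- as.logical(true_labels)
  if (length(pred_scores) != length(lab)) {
    stop("score and label lengths differ", call. = FALSE)
  }
  npos <- sum(lab); nneg <- sum(!lab)
  if (npos == 0L || nneg == 0L) {
    stop("AUC needs both classes present", call. = FALSE)
  }
  r <- rank(pred_scores, ties.method = "average")
  (sum(r[lab]) - npos * (npos + 1) / 2) / (npos * nneg)
}

#' ROC curve points
#'
#' Sweeps the decision threshold over the distinct prediction scores and
#' records the true- and false-positive rates, for plotting or CSV export
#' alongside [roc_auc()].
#'
#' @inheritParams roc_auc
#' @return Data frame with columns `threshold`, `tpr`, `fpr`, ordered from
#'   the most permissive to the strictest threshold.
#' @export
roc_points <- function(pred_scores, true_labels) {
  lab <- as.logical(true_labels)
  if (sum(lab) == 0L || sum(!lab) == 0L) {
    stop("ROC needs both classes present", call. = FALSE)
  }
  th <- c(-Inf, sort(unique(pred_scores)))
  data.frame(
    threshold = th,
    tpr = vapply(th, function(t) mean(pred_scores[lab] > t), numeric(1L)),
    fpr = vapply(th, function(t) mean(pred_scores[!lab] > t), numeric(1L))
  )
}

#' Seeded k-fold assignment
#'
#' Shuffles indices under the seed and chunks them contiguously into k
#' folds whose sizes differ by at most one.
#'
#' @param n Dataset size (must be at least `k`).
#' @param k Fold count (default 10).
#' @param seed Integer seed.
#' @return A `fold_assignment`: `n`, `k`, `seed`, and `fold_of`, an integer
#'   vector mapping each index to its fold.
#' @export
kfold_split <- function(n, k = 10L, seed = 1L) {
  if (n < k) stop("need n >= k for ", k, "-fold splitting", call. = FALSE)
  set.seed(seed)
  ord <- sample.int(n)
  sizes <- rep(n %/% k, k)
  extra <- n %% k
  if (extra > 0L) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  fold_of <- integer(n)
  fold_of[ord] <- rep(seq_len(k), times = sizes)
  structure(list(n = n, k = as.integer(k), seed = as.integer(seed),
                 fold_of = fold_of),
            class = "fold_assignment")
}

#' k-fold cross-validation of the affinity model
#'
#' Trains on k-1 folds and scores the held-out fold, repeating over all
#' folds; reports per-fold and mean regression (MSE, Pearson r) and
#' classification (Acc, Sn, Sp, MCC, AUC at the binder cutoff) metrics.
#' Deterministic for a fixed seed.
#'
#' @param dataset An `affinity_dataset` or plain sample list (see
#'   [train_affinity_model()]).
#' @param config A [gcn_config()]; fold models train with
#'   `config$seed + fold`.
#' @param k Fold count.
#' @param seed Seed for the fold assignment.
#' @return An `evaluation_report` list: `folds` (data frame of per-fold
#'   metrics), `mean` (named vector, NA-removed means), `k`, `seed`.
#' @export
cross_validate <- function(dataset, config = gcn_config(), k = 10L,
                           seed = 1L) {
  ds <- coerce_training_set(dataset)
  n <- nrow(ds$samples)
  fa <- kfold_split(n, k, seed)
  rows <- vector("list", k)
  for (fold in seq_len(k)) {
    test_idx <- which(fa$fold_of == fold)
    train_idx <- setdiff(seq_len(n), test_idx)
    sub <- ds
    sub$samples <- ds$samples[train_idx, , drop = FALSE]
    cfg <- config
    cfg$seed <- config$seed + fold
    model <- train_affinity_model(sub, cfg)
    pred <- vapply(test_idx, function(s) {
      predict_affinity(model,
                       ds$hla_graphs[[ds$samples$hla_id[s]]],
                       ds$pep_graphs[[as.character(ds$samples$pep_id[s])]])
    }, numeric(1L))
    truth <- ds$samples$y[test_idx]
    cc <- confusion_counts(pred, truth)
    met <- classification_metrics(cc)
    auc <- if (length(unique(truth > binder_cutoff_score())) == 2L) {
      roc_auc(pred, truth > binder_cutoff_score())
    } else {
      NA_real_
    }
    r <- if (stats::sd(pred) > 0 && stats::sd(truth) > 0) {
      stats::cor(pred, truth)
    } else {
      NA_real_
    }
    rows[[fold]] <- data.frame(
      fold = fold, n_test = length(test_idx),
      mse = mean((pred - truth)^2), pearson_r = r,
      Acc = met[["Acc"]], Sn = met[["Sn"]], Sp = met[["Sp"]],
      MCC = met[["MCC"]], AUC = auc
    )
  }
  folds <- do.call(rbind, rows)
  mean_row <- colMeans(folds[, -(1:2), drop = FALSE], na.rm = TRUE)
  structure(list(folds = folds, mean = mean_row, k = as.integer(k),
                 seed = as.integer(seed)),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat("<evaluation_report> ", x$k, "-fold CV (seed ", x$seed, ")\n",
      sep = "")
  print(round(x$mean, 4L))
  invisible(x)
}

#' Write an evaluation report to JSON
#'
#' @param report An `evaluation_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_evaluation_report <- function(report, path) {
  jsonlite::write_json(
    list(k = report$k, seed = report$seed,
         folds = report$folds, mean = as.list(report$mean)),
    path, auto_unbox = TRUE, digits = NA, dataframe = "columns", na = "null")
  invisible(path)
}
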