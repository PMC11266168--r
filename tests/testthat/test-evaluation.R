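# Confusion counting, the four classification metrics, AUC against the
# pairwise oracle, and fold assignment.

test_that("confusion counts binarize strictly at the cutoff", {
  cut <- binder_cutoff_score()
  same <- c(0.1, 0.5, 0.9, cut)
  cc <- confusion_counts(same, same)
  expect_equal(cc$FP + cc$FN, 0L)
  # everything predicted low, truth high
  cc2 <- confusion_counts(rep(0.1, 6), rep(0.9, 6))
  expect_equal(cc2$TP, 0L)
  expect_equal(cc2$FN, 6L)
  # hand-enumerated 10-pair case: 3 TP, 1 FP, 4 TN, 2 FN
  pred <- c(0.9, 0.8, 0.7, 0.6, 0.1, 0.2, 0.3, 0.2, 0.1, 0.3)
  true <- c(0.9, 0.8, 0.7, 0.1, 0.2, 0.1, 0.3, 0.2, 0.8, 0.9)
  cc3 <- confusion_counts(pred, true, cutoff = 0.5)
  expect_equal(unclass(cc3)[c("TP", "FP", "TN", "FN")],
               list(TP = 3L, FP = 1L, TN = 4L, FN = 2L))
  expect_error(confusion_counts(1:3 / 10, 1:2 / 10), "lengths differ")
})

test_that("metrics reproduce hand arithmetic and report NA when undefined", {
  perfect <- classification_metrics(list(TP = 5, TN = 5, FP = 0, FN = 0))
  expect_equal(unname(perfect[c("Acc", "MCC")]), c(1, 1))

  m <- classification_metrics(list(TP = 3, FP = 1, TN = 4, FN = 2))
  expect_equal(unname(m["Acc"]), 0.7)
  expect_equal(unname(m["Sn"]), 0.6)
  expect_equal(unname(m["Sp"]), 0.8)
  expect_equal(unname(m["MCC"]), 10 / sqrt(600))

  noneg <- classification_metrics(list(TP = 0, FN = 0, TN = 3, FP = 2))
  expect_true(is.na(noneg[["Sn"]]))
  expect_false(is.na(noneg[["Sp"]]))
})

test_that("MCC stays in [-1, 1] and flips sign with label swaps", {
  set.seed(11)
  for (trial in 1:50) {
    cc <- as.list(stats::setNames(sample(0:20, 4, replace = TRUE),
                                  c("TP", "TN", "FP", "FN")))
    m <- classification_metrics(cc)[["MCC"]]
    if (!is.na(m)) expect_true(m >= -1 && m <= 1)
    # swapping predictions: TP<->FP, TN<->FN
    sw <- list(TP = cc$FP, FP = cc$TP, TN = cc$FN, FN = cc$TN)
    ms <- classification_metrics(sw)[["MCC"]]
    if (!is.na(m) && !is.na(ms)) expect_equal(ms, -m, tolerance = 1e-12)
  }
})

test_that("AUC matches the brute-force pairwise oracle on small sets", {
  pairwise_auc <- function(scores, labels) {
    pos <- scores[labels]; neg <- scores[!labels]
    tot <- 0
    for (a in pos) for (b in neg) {
      tot <- tot + (a > b) + 0.5 * (a == b)
    }
    tot / (length(pos) * length(neg))
  }
  set.seed(23)
  for (trial in 1:30) {
    n <- sample(4:20, 1L)
    scores <- round(stats::runif(n), 1L)  # forces ties
    labels <- stats::runif(n) > 0.5
    if (!any(labels) || all(labels)) next
    expect_equal(roc_auc(scores, labels), pairwise_auc(scores, labels))
  }
  # perfect separation
  expect_equal(roc_auc(c(1, 2, 3, 10, 11), c(F, F, F, T, T)), 1)
  expect_error(roc_auc(1:4, rep(TRUE, 4)), "both classes")
})

test_that("random scores give AUC near one half", {
  set.seed(31)
  auc <- roc_auc(stats::runif(4000), stats::runif(4000) > 0.5)
  expect_lt(abs(auc - 0.5), 0.05)
})

test_that("AUC agrees with an established ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(41)
  scores <- stats::rnorm(60)
  labels <- stats::runif(60) > 0.4
  ref <- as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                        direction = "<")))
  expect_equal(roc_auc(scores, labels), ref, tolerance = 1e-12)
})

test_that("ROC points integrate to the rank AUC by trapezoids", {
  set.seed(47)
  scores <- stats::rnorm(40)
  labels <- stats::runif(40) > 0.5
  pts <- roc_points(scores, labels)
  # curve runs from (1,1) down to (0,0); trapezoid integral equals AUC
  o <- order(pts$fpr, pts$tpr)
  fpr <- pts$fpr[o]; tpr <- pts$tpr[o]
  auc <- sum(diff(fpr) * (utils::head(tpr, -1L) + utils::tail(tpr, -1L)) / 2)
  expect_equal(auc, roc_auc(scores, labels), tolerance = 1e-12)
  expect_equal(pts$tpr[1L], 1)
  expect_equal(pts$fpr[nrow(pts)], 0)
})

test_that("kfold_split partitions with near-equal sizes, deterministically", {
  fa <- kfold_split(100, 10, seed = 2)
  expect_equal(unname(table(fa$fold_of)), rep(10L, 10L),
               ignore_attr = TRUE)
  fa2 <- kfold_split(12, 10, seed = 3)
  expect_equal(sort(unname(table(fa2$fold_of)), decreasing = TRUE),
               c(2L, 2L, rep(1L, 8L)), ignore_attr = TRUE)
  expect_setequal(seq_len(12), which(fa2$fold_of %in% 1:10))
  expect_identical(kfold_split(50, 5, seed = 9)$fold_of,
                   kfold_split(50, 5, seed = 9)$fold_of)
  expect_error(kfold_split(5, 10), "n >= k")
})

test_that("cross-validation reports are deterministic given the seed", {
  ds <- fixture_dataset()
  sub <- ds
  sub$samples <- ds$samples[seq_len(40), , drop = FALSE]
  cfg <- gcn_config(n_epochs = 4, seed = 8)
  r1 <- cross_validate(sub, cfg, k = 4, seed = 6)
  r2 <- cross_validate(sub, cfg, k = 4, seed = 6)
  expect_identical(r1$folds, r2$folds)
  expect_equal(nrow(r1$folds), 4L)
  path1 <- withr::local_tempfile(fileext = ".json")
  path2 <- withr::local_tempfile(fileext = ".json")
  write_evaluation_report(r1, path1)
  write_evaluation_report(r2, path2)
  expect_identical(readLines(path1), readLines(path2))
})
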