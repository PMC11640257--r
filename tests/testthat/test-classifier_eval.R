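test_that("well-separated classes classify perfectly with a linear kernel", {
  ds <- separable_dataset(n = 30L, p = 5L, gap = 8)
  tr <- 1:20; te <- 21:30
  out <- train_and_score(ds$values[tr, ], ds$labels[tr], ds$values[te, ],
                         gene_subset(ds$gene_ids), classifier_config("linear"))
  expect_equal(out$labels, ds$labels[te])
  # decision scores are oriented: class-1 samples score higher
  expect_gt(min(out$scores[ds$labels[te] == 1L]),
            max(out$scores[ds$labels[te] == 0L]))
})

test_that("polynomial and rbf kernels are accepted and classify separable data", {
  ds <- separable_dataset(n = 40L, p = 4L, gap = 8)
  tr <- 1:30; te <- 31:40
  for (k in c("polynomial", "rbf")) {
    out <- train_and_score(ds$values[tr, ], ds$labels[tr], ds$values[te, ],
                           gene_subset(ds$gene_ids), classifier_config(k))
    expect_equal(out$labels, ds$labels[te])
  }
})

test_that("standardization uses training-fold statistics only", {
  ds <- separable_dataset(n = 30L, p = 4L, gap = 6)
  tr <- 1:20; te <- 21:30
  sub <- gene_subset(ds$gene_ids)
  cfg <- classifier_config("linear")
  base <- train_and_score(ds$values[tr, ], ds$labels[tr], ds$values[te, ],
                          sub, cfg)
  # shifting only the test matrix moves it off the training scale: scores
  # change, proving test data are scaled by train statistics
  shifted <- train_and_score(ds$values[tr, ], ds$labels[tr],
                             ds$values[te, ] + 50, sub, cfg)
  expect_false(isTRUE(all.equal(base$scores, shifted$scores)))
  # shifting train and test jointly is absorbed by the refitted scaler:
  # predictions are unchanged
  joint <- train_and_score(ds$values[tr, ] + 50, ds$labels[tr],
                           ds$values[te, ] + 50, sub, cfg)
  expect_equal(joint$labels, base$labels)
  expect_equal(joint$scores, base$scores, tolerance = 1e-6)
})

test_that("training is deterministic for identical inputs", {
  ds <- separable_dataset(n = 24L, p = 6L, gap = 3)
  tr <- 1:16; te <- 17:24
  sub <- gene_subset(ds$gene_ids)
  a <- train_and_score(ds$values[tr, ], ds$labels[tr], ds$values[te, ], sub)
  b <- train_and_score(ds$values[tr, ], ds$labels[tr], ds$values[te, ], sub)
  expect_identical(a, b)
})

test_that("single-class training folds are rejected at the fit level and skipped in CV", {
  ds <- separable_dataset(n = 12L, p = 3L)
  expect_error(train_and_score(ds$values[c(1, 3, 5), ], rep(0L, 3),
                               ds$values[7:8, ], gene_subset(ds$gene_ids)),
               "single class")
})

test_that("leave-one-out evaluation matches hand-enumerated folds", {
  # perfectly separable data -> LOOCV accuracy 1
  ds <- separable_dataset(n = 20L, p = 4L, gap = 8)
  loo <- loocv_accuracy(ds, gene_subset(ds$gene_ids))
  expect_equal(loo$accuracy, 1.0)
  cm <- loo$confusion
  expect_equal(cm$tp + cm$tn + cm$fp + cm$fn, 20L)
  expect_equal(cm$fp + cm$fn, 0L)

  # 8-sample fixture: sample s4 (x = 3, inside the low cluster) is
  # mislabeled 1 relative to the perfect threshold rule x > 10. In every
  # fold the soft margin pays the slack for that one outlier rather than
  # squeezing between 2 and 3, so the boundary stays in the wide gap and
  # only the mislabeled fold errs -> 7/8
  values <- matrix(c(0, 1, 2, 3, 20, 21, 22, 23), 8, 1)
  ds8 <- expression_dataset(values, paste0("s", 1:8), "G1",
                            c(0L, 0L, 0L, 1L, 1L, 1L, 1L, 1L))
  loo8 <- loocv_accuracy(ds8, gene_subset("G1"), classifier_config("linear"))
  expect_equal(loo8$accuracy, 0.875)
  expect_equal(loo8$predicted, c(0L, 0L, 0L, 0L, 1L, 1L, 1L, 1L))

  # a singleton class cannot be held out: clear domain error
  ds_bad <- expression_dataset(matrix(c(0, 1, 10, 11), 4, 1),
                               paste0("s", 1:4), "G1", c(0L, 0L, 0L, 1L))
  expect_error(loocv_accuracy(ds_bad, gene_subset("G1")), "per class")
})

test_that("LOOCV equals n-fold cross-validation with k = n", {
  ds <- separable_dataset(n = 15L, p = 3L, gap = 2, seed = 5)
  sub <- gene_subset(ds$gene_ids)
  loo <- loocv_accuracy(ds, sub)
  err_n <- cv_error(ds, sub, k = n_samples(ds))
  expect_equal(1 - loo$accuracy, err_n)
})

test_that("under label permutation LOOCV accuracy collapses to chance", {
  ds <- separable_dataset(n = 20L, p = 5L, gap = 6, seed = 9)
  sub <- gene_subset(ds$gene_ids)
  accs <- vapply(1:25, function(s) {
    set.seed(5000 + s)
    perm <- expression_dataset(ds$values, ds$sample_ids, ds$gene_ids,
                               sample(ds$labels))
    loocv_accuracy(perm, sub)$accuracy
  }, numeric(1))
  majority <- max(mean(ds$labels), 1 - mean(ds$labels))
  se <- sd(accs) / sqrt(length(accs))
  expect_lt(abs(mean(accs) - majority), max(3 * se, 0.12))
})

test_that("metric formulas reproduce the brute-force grid of confusion matrices", {
  for (tp in 0:5) for (tn in 0:5) for (fp in 0:5) for (fn in 0:5) {
    if (tp + tn + fp + fn == 0) next
    cm <- structure(list(tp = tp, tn = tn, fp = fp, fn = fn),
                    class = "ConfusionMatrix")
    m <- classification_metrics(cm)
    expect_equal(unname(m["acc"]), (tp + tn) / (tp + tn + fp + fn))
    expect_equal(unname(m["precision"]), if (tp + fp == 0) 0 else tp / (tp + fp))
    expect_equal(unname(m["recall"]), if (tp + fn == 0) 0 else tp / (tp + fn))
    p <- if (tp + fp == 0) 0 else tp / (tp + fp)
    sn <- if (tp + fn == 0) 0 else tp / (tp + fn)
    expect_equal(unname(m["f_score"]),
                 if (p + sn == 0) 0 else 2 * p * sn / (p + sn))
  }
  # degenerate denominators are flagged
  m0 <- classification_metrics(confusion_matrix(c(1L, 1L), c(0L, 0L)))
  expect_true("precision" %in% attr(m0, "undefined"))
  # perfect classifier
  mp <- classification_metrics(confusion_matrix(c(0L, 1L), c(0L, 1L)))
  expect_equal(as.numeric(mp), c(1, 1, 1, 1))
})

test_that("ROC AUC equals the pairwise concordance statistic", {
  # hand oracle: labels [0,0,1,1], scores [0.1,0.4,0.35,0.8] -> 3/4
  cv <- curves(c(0L, 0L, 1L, 1L), c(0.1, 0.4, 0.35, 0.8))
  expect_equal(cv$auc_roc, 0.75)
  set.seed(808)
  for (i in 1:100) {
    n <- sample(6:50, 1)
    labels <- sample(0:1, n, replace = TRUE)
    if (length(unique(labels)) < 2) labels[1:2] <- 0:1
    scores <- round(rnorm(n), sample(0:2, 1)) # rounding induces ties
    cv <- curves(labels, scores)
    expect_equal(cv$auc_roc, concordance_auc(labels, scores),
                 tolerance = 1e-12)
  }
})

test_that("ROC points are anchored and monotone; perfect ranking gives AUC 1", {
  cv <- curves(c(0L, 1L, 0L, 1L), c(0, 1, 0, 1))
  expect_equal(cv$auc_roc, 1.0)
  expect_equal(cv$roc_points$fpr[1], 0)
  expect_equal(cv$roc_points$tpr[1], 0)
  expect_equal(tail(cv$roc_points$fpr, 1), 1)
  expect_equal(tail(cv$roc_points$tpr, 1), 1)
  expect_true(all(diff(cv$roc_points$fpr) >= 0))
  expect_true(all(diff(cv$roc_points$tpr) >= 0))
  expect_error(curves(c(1L, 1L), c(0.2, 0.3)), "both classes")
})

test_that("AUC agrees with an established implementation on a random instance", {
  skip_if_not_installed("pROC")
  set.seed(14)
  labels <- sample(0:1, 40, replace = TRUE); labels[1:2] <- 0:1
  scores <- rnorm(40) + labels
  ours <- curves(labels, scores)$auc_roc
  ref <- as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                        direction = "<")))
  expect_equal(ours, ref, tolerance = 1e-12)
})

test_that("uninformative scores give AUC near one half", {
  set.seed(909)
  aucs <- vapply(1:100, function(i) {
    labels <- sample(0:1, 1000, replace = TRUE)
    curves(labels, rnorm(1000))$auc_roc
  }, numeric(1))
  expect_lt(abs(mean(aucs) - 0.5), 0.02)
})

test_that("run summaries give max, mean and min", {
  expect_equal(summarize_runs(c(0.9, 0.8, 0.85)),
               c(best = 0.9, average = 0.85, worst = 0.8))
  expect_equal(summarize_runs(0.7), c(best = 0.7, average = 0.7, worst = 0.7))
  expect_equal(unname(summarize_runs(rep(0.5, 4))), rep(0.5, 3))
  expect_error(summarize_runs(numeric(0)), "no run")
})
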