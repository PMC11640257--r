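# Wrapped SVM classification and the evaluation metrics/curves used both
# inside the swarm fitness and for final reporting. The SVM itself is
# delegated to libsvm via e1071; this module owns kernels-as-configuration,
# fold construction, train-only standardization, confusion-matrix metrics
# and ROC/PR curve construction.

#' Configuration for the wrapped support-vector classifier
#'
#' @param kernel One of `"linear"`, `"polynomial"`, `"rbf"`.
#' @param C Soft-margin cost (default 1).
#' @param gamma Kernel coefficient for polynomial/RBF; `NULL` uses the
#'   1 / (n_features * variance of the pooled training values) convention.
#' @param degree Polynomial degree (default 3).
#' @param coef0 Polynomial offset term (default 0).
#' @param standardize Standardize each gene to zero mean / unit variance
#'   using training-fold statistics only (default `TRUE`).
#' @return An object of class `ClassifierConfig`.
#' @export
classifier_config <- function(kernel = c("linear", "polynomial", "rbf"),
                              C = 1, gamma = NULL, degree = 3L, coef0 = 0,
                              standardize = TRUE) {
  kernel <- match.arg(kernel)
  if (C <= 0) stop("C must be > 0")
  if (!is.null(gamma) && gamma <= 0) stop("gamma must be > 0")
  if (degree < 1L) stop("degree must be >= 1")
  structure(list(kernel = kernel, C = as.double(C), gamma = gamma,
                 degree = as.integer(degree), coef0 = as.double(coef0),
                 standardize = isTRUE(standardize)),
            class = "ClassifierConfig")
}

# Map our kernel names onto e1071/libsvm names.
.svm_kernel <- c(linear = "linear", polynomial = "polynomial", rbf = "radial")

#' Train an SVM on one fold and score held-out samples
#'
#' Columns are restricted to `subset`; if `cfg$standardize`, per-gene mean
#' and standard deviation are fitted on the training matrix only and applied
#' to both matrices (zero-variance genes pass through unscaled), so no
#' information leaks from test to train. Returns hard 0/1 labels and a
#' real-valued decision score oriented so larger means more class-1
#' ("Cancer").
#'
#' @param train_values,train_labels Training expression matrix (samples x
#'   genes, with gene column names) and 0/1 labels; both classes required.
#' @param test_values Held-out matrix with the same columns.
#' @param subset `GeneSubset` (or character vector) of genes to use.
#' @param cfg A [classifier_config()].
#' @return List with `labels` (integer 0/1 predictions) and `scores`
#'   (numeric decision values).
#' @export
train_and_score <- function(train_values, train_labels, test_values, subset,
                            cfg = classifier_config()) {
  ids <- if (inherits(subset, "GeneSubset")) subset$gene_ids else as.character(subset)
  if (length(ids) == 0L) stop("gene subset is empty")
  if (length(unique(train_labels)) < 2L)
    stop("training fold contains a single class")
  xtr <- train_values[, ids, drop = FALSE]
  xte <- test_values[, ids, drop = FALSE]
  if (cfg$standardize) {
    mu <- colMeans(xtr)
    sd <- apply(xtr, 2L, stats::sd)
    sd[sd == 0 | is.na(sd)] <- 1
    xtr <- sweep(sweep(xtr, 2L, mu), 2L, sd, "/")
    xte <- sweep(sweep(xte, 2L, mu), 2L, sd, "/")
  }
  gamma <- cfg$gamma
  if (is.null(gamma)) {
    v <- stats::var(as.vector(xtr))
    gamma <- if (is.na(v) || v == 0) 1 / ncol(xtr) else 1 / (ncol(xtr) * v)
  }
  fit <- e1071::svm(xtr, factor(train_labels, levels = c(0L, 1L)),
                    kernel = .svm_kernel[[cfg$kernel]], cost = cfg$C,
                    gamma = gamma, degree = cfg$degree, coef0 = cfg$coef0,
                    scale = FALSE)
  pred <- stats::predict(fit, xte, decision.values = TRUE)
  dv <- attr(pred, "decision.values")
  scores <- as.numeric(dv[, 1L])
  # libsvm orients the decision value toward its first training class;
  # flip so positive always means class 1
  if (colnames(dv)[1L] == "0/1") scores <- -scores
  list(labels = as.integer(as.character(pred)), scores = scores)
}

#' Confusion matrix for binary predictions
#'
#' Class 1 ("Cancer") is the positive class.
#'
#' @param truth,predicted Integer 0/1 vectors of equal length.
#' @return An object of class `ConfusionMatrix` with fields `tp`, `tn`,
#'   `fp`, `fn`.
#' @export
confusion_matrix <- function(truth, predicted) {
  stopifnot(length(truth) == length(predicted))
  structure(list(tp = sum(truth == 1L & predicted == 1L),
                 tn = sum(truth == 0L & predicted == 0L),
                 fp = sum(truth == 0L & predicted == 1L),
                 fn = sum(truth == 1L & predicted == 0L)),
            class = "ConfusionMatrix")
}

#' Accuracy, precision, sensitivity and F-score from a confusion matrix
#'
#' ACC = (TP+TN)/(TP+TN+FP+FN); P = TP/(TP+FP); Sn = TP/(TP+FN);
#' F = 2 P Sn / (P + Sn). A metric whose denominator is zero is reported as
#' 0 and flagged in the `undefined` attribute.
#'
#' @param cm A [confusion_matrix()] (or list with tp/tn/fp/fn).
#' @return Named numeric vector `c(acc, precision, recall, f_score)` with an
#'   `undefined` attribute naming any degenerate metrics.
#' @export
classification_metrics <- function(cm) {
  tp <- cm$tp; tn <- cm$tn; fp <- cm$fp; fn <- cm$fn
  total <- tp + tn + fp + fn
  if (total == 0L) stop("empty confusion matrix")
  undefined <- character(0)
  acc <- (tp + tn) / total
  if (tp + fp == 0) { p <- 0; undefined <- c(undefined, "precision") }
  else p <- tp / (tp + fp)
  if (tp + fn == 0) { sn <- 0; undefined <- c(undefined, "recall") }
  else sn <- tp / (tp + fn)
  if (p + sn == 0) { f <- 0; undefined <- c(undefined, "f_score") }
  else f <- 2 * p * sn / (p + sn)
  structure(c(acc = acc, precision = p, recall = sn, f_score = f),
            undefined = undefined)
}

# Stratified k-fold assignment: samples of each class are shuffled and dealt
# round-robin, so every fold gets a near-proportional share of both classes.
stratified_folds <- function(labels, k, seed = NULL) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  if (!is.null(seed)) set.seed(seed)
  fold <- integer(length(labels))
  for (cls in unique(labels)) {
    idx <- which(labels == cls)
    idx <- if (length(idx) > 1L) sample(idx) else idx
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

#' Cross-validated misclassification error on a gene subset
#'
#' Stratified k-fold cross-validation of the wrapped SVM. Folds whose
#' training portion ends up single-class (possible on tiny inputs) are
#' skipped with a warning and the denominator adjusts.
#'
#' @param dataset An [expression_dataset()].
#' @param subset Genes to use.
#' @param cfg A [classifier_config()].
#' @param k Number of folds (default 5, clamped to `n_samples`).
#' @param seed Seed for the fold shuffle.
#' @return Misclassification rate in `[0, 1]`.
#' @export
cv_error <- function(dataset, subset, cfg = classifier_config(), k = 5L,
                     seed = 1L) {
  k <- min(as.integer(k), n_samples(dataset))
  fold <- stratified_folds(dataset$labels, k, seed)
  wrong <- 0L; total <- 0L
  for (f in seq_len(k)) {
    te <- fold == f
    if (!any(te)) next
    if (length(unique(dataset$labels[!te])) < 2L) {
      warning("skipping fold ", f, ": single-class training portion")
      next
    }
    out <- train_and_score(dataset$values[!te, , drop = FALSE],
                           dataset$labels[!te],
                           dataset$values[te, , drop = FALSE], subset, cfg)
    wrong <- wrong + sum(out$labels != dataset$labels[te])
    total <- total + sum(te)
  }
  if (total == 0L) stop("no usable folds")
  wrong / total
}

#' Leave-one-out cross-validated accuracy
#'
#' One fold per sample; accuracy is correct/total and the per-fold
#' predictions are aggregated into a single confusion matrix. The held-out
#' decision scores are returned for curve construction.
#'
#' @param dataset An [expression_dataset()] with at least 3 samples and both
#'   classes present.
#' @param subset Genes to use.
#' @param cfg A [classifier_config()].
#' @return List with `accuracy`, `confusion` (a `ConfusionMatrix`),
#'   `predicted` and `scores` (per-sample held-out decision values).
#' @export
loocv_accuracy <- function(dataset, subset, cfg = classifier_config()) {
  n <- n_samples(dataset)
  if (n < 3L) stop("leave-one-out evaluation needs at least 3 samples")
  if (min(tabulate(dataset$labels + 1L, 2L)) < 2L)
    stop("leave-one-out evaluation needs at least 2 samples per class ",
         "(holding out a singleton class leaves a single-class training fold)")
  predicted <- integer(n)
  scores <- numeric(n)
  for (i in seq_len(n)) {
    out <- train_and_score(dataset$values[-i, , drop = FALSE],
                           dataset$labels[-i],
                           dataset$values[i, , drop = FALSE], subset, cfg)
    predicted[i] <- out$labels
    scores[i] <- out$scores
  }
  cm <- confusion_matrix(dataset$labels, predicted)
  list(accuracy = mean(predicted == dataset$labels), confusion = cm,
       predicted = predicted, scores = scores)
}

#' ROC and precision-recall curves from decision scores
#'
#' Sweeps the threshold across the unique scores (predict 1 when
#' score >= threshold). ROC points (FPR, TPR) are anchored at (0,0) and
#' (1,1); the area under the ROC curve is computed by the trapezoid rule,
#' which for a score-rank sweep equals the Mann-Whitney concordance
#' probability with ties counted 1/2. PR points come from the same sweep.
#'
#' @param labels Integer 0/1 vector; both classes must be present.
#' @param scores Numeric decision scores, larger meaning more class-1.
#' @return List with `roc_points` (data frame fpr/tpr), `pr_points`
#'   (data frame recall/precision) and `auc_roc`.
#' @export
curves <- function(labels, scores) {
  stopifnot(length(labels) == length(scores))
  n_pos <- sum(labels == 1L)
  n_neg <- sum(labels == 0L)
  if (n_pos == 0L || n_neg == 0L)
    stop("both classes must be present to construct curves")
  ord <- order(scores, decreasing = TRUE)
  lab <- labels[ord]
  sc <- scores[ord]
  # cumulative counts at each distinct threshold (ties grouped)
  last_of_tie <- c(sc[-length(sc)] != sc[-1L], TRUE)
  tp <- cumsum(lab == 1L)[last_of_tie]
  fp <- cumsum(lab == 0L)[last_of_tie]
  tpr <- c(0, tp / n_pos, 1)
  fpr <- c(0, fp / n_neg, 1)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  pr <- data.frame(recall = tp / n_pos, precision = tp / (tp + fp))
  list(roc_points = data.frame(fpr = fpr, tpr = tpr),
       pr_points = pr, auc_roc = auc)
}

#' Best / average / worst of a set of per-run accuracies
#'
#' @param per_run_accuracies Non-empty numeric vector.
#' @return Named numeric vector `c(best, average, worst)`.
#' @export
summarize_runs <- function(per_run_accuracies) {
  if (length(per_run_accuracies) == 0L) stop("no run accuracies to summarize")
  c(best = max(per_run_accuracies), average = mean(per_run_accuracies),
    worst = min(per_run_accuracies))
}

#' Assemble an evaluation report
#'
#' @param confusion A `ConfusionMatrix`.
#' @param roc_points,pr_points Curve point data frames from [curves()].
#' @param auc_roc Area under the ROC curve.
#' @param per_run_accuracies Accuracy per repeated run.
#' @return An object of class `EvaluationReport` holding the confusion
#'   matrix, the four scalar metrics, both curves, AUC, and the per-run
#'   best/average/worst summary.
#' @export
evaluation_report <- function(confusion, roc_points, pr_points, auc_roc,
                              per_run_accuracies) {
  m <- classification_metrics(confusion)
  s <- summarize_runs(per_run_accuracies)
  structure(list(confusion = confusion,
                 accuracy = unname(m["acc"]), precision = unname(m["precision"]),
                 recall = unname(m["recall"]), f_score = unname(m["f_score"]),
                 roc_points = roc_points, pr_points = pr_points,
                 auc_roc = auc_roc,
                 per_run_accuracies = as.double(per_run_accuracies),
                 best = unname(s["best"]), average = unname(s["average"]),
                 worst = unname(s["worst"])),
            class = "EvaluationReport")
}

#' @export
print.EvaluationReport <- function(x, ...) {
  cat(sprintf("EvaluationReport: ACC %.4f  P %.4f  Sn %.4f  F %.4f  AUC %.4f\n",
              x$accuracy, x$precision, x$recall, x$f_score, x$auc_roc))
  cat(sprintf("runs: best %.4f  average %.4f  worst %.4f (n = %d)\n",
              x$best, x$average, x$worst, length(x$per_run_accuracies)))
  invisible(x)
}
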