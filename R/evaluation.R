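#' Confusion matrix with HGG as the positive class
#'
#' @param truth,pred Binary labels (`"HGG"`/`"LGG"` or 0/1), equal length.
#' @return Object of class `confusion_matrix`: list with integer `TP`,
#'   `TN`, `FP`, `FN`.
#' @export
confusion <- function(truth, pred) {
  y <- .as_binary_labels(truth)
  p <- .as_binary_labels(pred)
  if (length(y) != length(p)) {
    stop(sprintf("confusion: %d truth labels vs %d predictions",
                 length(y), length(p)))
  }
  if (length(y) < 1L) stop("confusion: need at least one sample")
  structure(
    list(TP = sum(y == 1 & p == 1), TN = sum(y == 0 & p == 0),
         FP = sum(y == 0 & p == 1), FN = sum(y == 1 & p == 0)),
    class = "confusion_matrix"
  )
}

#' Classification metrics from a confusion matrix
#'
#' Accuracy `(TP+TN)/n`, recall/sensitivity `TP/(TP+FN)`, specificity
#' `TN/(TN+FP)`, precision `TP/(TP+FP)` and the F1 harmonic mean
#' `2*Pre*Rec/(Pre+Rec)`.  A metric whose denominator is zero is reported
#' as `NA` (explicitly undefined), never silently as 0.
#'
#' @param cm A [confusion()] result.
#' @return Named list: `ACC`, `Rec`, `Spe`, `Pre`, `F1`, `n`.
#' @export
classification_metrics <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  n <- cm$TP + cm$TN + cm$FP + cm$FN
  if (n == 0) stop("classification_metrics: empty confusion matrix")
  safe_div <- function(a, b) if (b == 0) NA_real_ else a / b
  rec <- safe_div(cm$TP, cm$TP + cm$FN)
  spe <- safe_div(cm$TN, cm$TN + cm$FP)
  pre <- safe_div(cm$TP, cm$TP + cm$FP)
  f1 <- if (is.na(pre) || is.na(rec) || (pre + rec) == 0) NA_real_ else
    2 * pre * rec / (pre + rec)
  list(ACC = (cm$TP + cm$TN) / n, Rec = rec, Spe = spe, Pre = pre,
       F1 = f1, n = n)
}

#' Mean absolute and root-mean-square error of probability scores
#'
#' `MAE = mean(|y_i - x_i|)` and `RMSE = sqrt(mean((y_i - x_i)^2))` for
#' predicted probabilities `x_i` against 0/1 truth `y_i`.
#'
#' @param scores Predicted probabilities in `[0, 1]`.
#' @param labels Binary truth labels.
#' @return List with `MAE` and `RMSE`.
#' @export
error_metrics <- function(scores, labels) {
  y <- .as_binary_labels(labels)
  if (length(scores) != length(y)) stop("error_metrics: length mismatch")
  if (any(!is.finite(scores)) || any(scores < 0) || any(scores > 1)) {
    stop("error_metrics: scores must be probabilities in [0, 1]")
  }
  e <- y - scores
  list(MAE = mean(abs(e)), RMSE = sqrt(mean(e^2)))
}

#' ROC area under the curve
#'
#' Computed two ways that must agree to 1e-12: a threshold sweep over the
#' unique scores with trapezoidal integration of the ROC curve, and the
#' Mann-Whitney rank-sum statistic with half credit for tied scores.
#'
#' @param scores Numeric scores (higher = more HGG-like).
#' @param labels Binary truth labels; both classes must be present.
#' @return Scalar AUC in `[0, 1]`.
#' @export
roc_auc <- function(scores, labels) {
  y <- .as_binary_labels(labels)
  if (length(scores) != length(y)) stop("roc_auc: length mismatch")
  if (length(unique(y)) < 2L) stop("roc_auc: both classes must be present")
  n1 <- sum(y == 1); n0 <- sum(y == 0)

  # threshold sweep: one operating point per unique score, plus extremes
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE), -Inf)
  tpr <- vapply(thr, function(t) sum(scores >= t & y == 1) / n1, numeric(1))
  fpr <- vapply(thr, function(t) sum(scores >= t & y == 0) / n0, numeric(1))
  auc_trap <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)

  # rank-sum equivalence (ties get half credit)
  r <- rank(scores)
  auc_rank <- (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)

  if (abs(auc_trap - auc_rank) > 1e-12) {
    stop(sprintf("roc_auc: internal cross-check failed (%.15f vs %.15f)",
                 auc_trap, auc_rank))
  }
  auc_rank
}

#' Stratified K-fold cross-validation of the full pipeline
#'
#' Splits the cohort's cases into K stratified folds (per-class fold sizes
#' differ by at most one), runs the complete two-stage training on each
#' K-1 fold training set and evaluates accuracy on the held-out fold.
#'
#' @param cohort A [generate_cohort()] result; all samples are used
#'   regardless of their original split tag.
#' @param K Fold count; must not exceed the minority-class size.
#' @param spec A [network_spec()].
#' @param cfg A [train_config()]; its `stage1_subset_size` must fit the
#'   smallest fold-complement.
#' @param seed Seed for the fold assignment.
#' @return List: `mean_accuracy`, `sd_accuracy`, `per_fold` (data.frame
#'   with fold, n_test, accuracy).
#' @export
kfold_crossval <- function(cohort, K, spec = network_spec(),
                           cfg = train_config(), seed = 1L) {
  samples <- cohort$samples
  labels <- vapply(samples, function(s) s$label, character(1))
  K <- as.integer(K)
  n_min <- min(table(labels))
  if (K < 2L || K > n_min) {
    stop(sprintf("K must be between 2 and the minority-class count (%d)", n_min))
  }
  fold <- integer(length(samples))
  withr::with_seed(seed, {
    for (cl in unique(labels)) {
      idx <- which(labels == cl)
      fold[idx] <- sample(rep_len(seq_len(K), length(idx)))
    }
  })
  acc <- numeric(K)
  n_test <- integer(K)
  for (k in seq_len(K)) {
    tr <- samples[fold != k]
    te <- samples[fold == k]
    tr <- lapply(tr, function(s) { s$split <- "train"; s })
    model <- train_model(list(samples = tr), spec, cfg)
    pred <- predict(model, te, type = "label")
    truth <- vapply(te, function(s) s$label, character(1))
    acc[k] <- mean(pred == truth)
    n_test[k] <- length(te)
  }
  list(mean_accuracy = mean(acc),
       sd_accuracy = stats::sd(acc),
       per_fold = data.frame(fold = seq_len(K), n_test = n_test,
                             accuracy = acc),
       fold_assignment = fold)
}
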