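# LDA classification, grouped cross-trial validation, and confusion metrics.

#' Fit a linear discriminant classifier
#'
#' Gaussian equal-covariance LDA: class means, pooled within-class covariance
#' with a ridge (`shrinkage * mean(diag)` added to the diagonal, so duplicate
#' or collinear features do not break the solve), empirical priors. Ties in
#' the discriminant scores go to the baseline (negative) class.
#'
#' @param features A [feature_table()] with exactly two classes.
#' @param shrinkage Relative ridge on the pooled covariance diagonal.
#' @param positive_label Class treated as positive ("mi"): the FPR then
#'   measures baseline windows misread as MI.
#' @return An `lda_model`.
#' @export
fit_lda <- function(features, shrinkage = 1e-6, positive_label = "mi") {
  x <- feature_matrix(features)
  y <- features$label
  classes <- unique(y)
  if (length(classes) != 2) {
    abort("LDA needs exactly two classes, got %d", length(classes))
  }
  # order classes (negative, positive) when the positive label is present
  if (positive_label %in% classes) {
    classes <- c(setdiff(classes, positive_label), positive_label)
  }
  means <- lapply(classes, function(k) colMeans(x[y == k, , drop = FALSE]))
  names(means) <- classes
  f <- ncol(x)
  sw <- matrix(0, f, f)
  for (k in classes) {
    xi <- x[y == k, , drop = FALSE]
    xi <- sweep(xi, 2, means[[k]])
    sw <- sw + crossprod(xi)
  }
  pooled <- sw / (nrow(x) - 2)
  pooled <- pooled + diag(shrinkage * mean(diag(pooled)), f)
  priors <- as.numeric(table(factor(y, levels = classes))) / length(y)
  names(priors) <- classes
  structure(list(class_means = means,
                 pooled_covariance = pooled,
                 priors = priors,
                 shrinkage = shrinkage,
                 classes = classes,
                 positive_label = if (positive_label %in% classes)
                   positive_label else classes[2],
                 feature_names = colnames(x)),
            class = "lda_model")
}

#' Predict class labels with a fitted LDA
#'
#' @param object An `lda_model`.
#' @param newdata A [feature_table()] or numeric matrix.
#' @param ... Unused.
#' @return Character vector of predicted labels.
#' @export
predict.lda_model <- function(object, newdata, ...) {
  x <- if (inherits(newdata, "feature_table")) feature_matrix(newdata)
       else as.matrix(newdata)
  sinv <- solve(object$pooled_covariance)
  scores <- vapply(object$classes, function(k) {
    mu <- object$class_means[[k]]
    a <- sinv %*% mu
    as.numeric(x %*% a) - 0.5 * sum(mu * a) + log(object$priors[[k]])
  }, numeric(nrow(x)))
  scores <- matrix(scores, nrow = nrow(x))
  # ties -> the class listed first (the baseline / negative class)
  object$classes[max.col(scores, ties.method = "first")]
}

#' Tally a binary confusion matrix
#'
#' @param truth,predicted Label vectors.
#' @param positive_label The positive class.
#' @return A `confusion_counts` list: `TP`, `TN`, `FP`, `FN`,
#'   `positive_label`.
#' @export
confusion_counts <- function(truth, predicted, positive_label = "mi") {
  pos_t <- truth == positive_label
  pos_p <- predicted == positive_label
  structure(list(TP = sum(pos_t & pos_p),
                 TN = sum(!pos_t & !pos_p),
                 FP = sum(!pos_t & pos_p),
                 FN = sum(pos_t & !pos_p),
                 positive_label = positive_label),
            class = "confusion_counts")
}

#' Accuracy and false-positive rate from confusion counts
#'
#' `ACC = (TP + TN) / (TP + FN + FP + TN)` and `FPR = FP / (FP + TN)`.
#'
#' @param counts A [confusion_counts()] (or list with TP/TN/FP/FN).
#' @return Named numeric `c(ACC, FPR)`.
#' @export
confusion_metrics <- function(counts) {
  total <- counts$TP + counts$TN + counts$FP + counts$FN
  if (total <= 0) abort("empty confusion matrix")
  if (any(c(counts$TP, counts$TN, counts$FP, counts$FN) < 0)) {
    abort("negative confusion counts")
  }
  if (counts$FP + counts$TN == 0) {
    abort("FPR undefined: no negative-class rows (FP + TN = 0)")
  }
  c(ACC = (counts$TP + counts$TN) / total,
    FPR = counts$FP / (counts$FP + counts$TN))
}

# optionally collapse window-level predictions to one per group by
# majority vote; ties go to the negative (non-positive) class
score_predictions <- function(truth, pred, groups, positive_label, vote,
                              negative_label) {
  if (!isTRUE(vote)) return(list(truth = truth, pred = pred))
  g <- unique(groups)
  voted <- vapply(g, function(gr) {
    p <- pred[groups == gr]
    if (sum(p == positive_label) > length(p) / 2) positive_label
    else negative_label
  }, character(1))
  truth_g <- vapply(g, function(gr) truth[groups == gr][1], character(1))
  list(truth = truth_g, pred = voted)
}

#' Stratified assignment of trial groups to folds
#'
#' Groups (source trials) are permuted with the given seed separately within
#' each class and dealt round-robin to `k` folds, so every fold tests on at
#' least one group of each class when each class has at least `k` groups.
#'
#' @param groups,labels Per-row group ids and class labels.
#' @param k Number of folds.
#' @param seed Permutation seed.
#' @return Named integer vector: fold per unique group.
#' @export
make_group_folds <- function(groups, labels, k = 5, seed = 1L) {
  gl <- unique(data.frame(group = groups, label = labels,
                          stringsAsFactors = FALSE))
  if (anyDuplicated(gl$group)) {
    abort("a group id spans both classes; group labels must be class-pure")
  }
  fold <- integer(nrow(gl))
  names(fold) <- gl$group
  with_seed(seed, {
    for (cl in unique(gl$label)) {
      g <- gl$group[gl$label == cl]
      if (length(g) < k) {
        abort("class '%s' has %d groups, fewer than k = %d folds",
              cl, length(g), k)
      }
      g <- sample(g)
      fold[g] <- rep_len(seq_len(k), length(g))
    }
  })
  fold
}

#' Grouped k-fold cross-validation of an LDA on a feature table
#'
#' Folds partition trial groups (source trials), never rows: all windows cut
#' from one trial stay on the same side of every split, the leakage guard of
#' cross-trial validation. Per fold an LDA is fitted on the training-group
#' rows and scored on the test-group rows (each window scored individually;
#' no per-trial vote); ACC and FPR are computed per fold and averaged
#' arithmetically (macro) over folds.
#'
#' @param features A [feature_table()].
#' @param k Number of folds.
#' @param seed Seed for the group-to-fold permutation.
#' @param shrinkage Passed to [fit_lda()].
#' @param positive_label Positive class for the confusion matrix.
#' @param vote Aggregate window predictions to one per group by majority
#'   vote (ties to the negative class) before scoring; off by default —
#'   standard scoring is per window.
#' @return An `eval_result`: `per_fold` data frame (fold, acc, fpr, tp, tn,
#'   fp, fn), `mean_acc`, `mean_fpr`, `fold_of_group`, `k`, `seed`.
#' @export
cross_validate <- function(features, k = 5, seed = 1L, shrinkage = 1e-6,
                           positive_label = "mi", vote = FALSE) {
  fold_of_group <- make_group_folds(features$group, features$label, k, seed)
  row_fold <- fold_of_group[features$group]
  per_fold <- lapply(seq_len(k), function(f) {
    train <- features[row_fold != f, , drop = FALSE]
    test <- features[row_fold == f, , drop = FALSE]
    model <- fit_lda(train, shrinkage = shrinkage,
                     positive_label = positive_label)
    pred <- predict(model, test)
    scored <- score_predictions(test$label, pred, test$group,
                                model$positive_label, vote,
                                model$classes[1])
    cnt <- confusion_counts(scored$truth, scored$pred, model$positive_label)
    m <- confusion_metrics(cnt)
    data.frame(fold = f, acc = m[["ACC"]], fpr = m[["FPR"]],
               tp = cnt$TP, tn = cnt$TN, fp = cnt$FP, fn = cnt$FN)
  })
  per_fold <- do.call(rbind, per_fold)
  structure(list(per_fold = per_fold,
                 mean_acc = mean(per_fold$acc),
                 mean_fpr = mean(per_fold$fpr),
                 fold_of_group = fold_of_group,
                 k = as.integer(k),
                 seed = as.integer(seed)),
            class = "eval_result")
}

#' @export
print.eval_result <- function(x, ...) {
  cat(sprintf("<eval_result> %d folds | mean ACC %.3f | mean FPR %.3f\n",
              x$k, x$mean_acc, x$mean_fpr))
  invisible(x)
}
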