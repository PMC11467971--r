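# LDA, grouped cross-validation, and confusion metrics.

sep_features <- function(n = 30, gap = 10, seed = 1) {
  withr::with_seed(seed, {
    x <- rbind(matrix(rnorm(n * 2), n), matrix(rnorm(n * 2) + gap, n))
    feature_table(x, rep(c("baseline", "mi"), each = n),
                  rep(NA_character_, 2 * n), paste0("g", seq_len(2 * n)))
  })
}

test_that("LDA separates distant clouds and matches MASS on common data", {
  ft <- sep_features()
  m <- fit_lda(ft)
  expect_identical(unname(predict(m, ft)), ft$label)
  skip_if_not_installed("MASS")
  # cross-check on overlapping clouds against the reference implementation
  ft2 <- sep_features(gap = 1.5, seed = 9)
  ours <- predict(fit_lda(ft2), ft2)
  x <- feature_matrix(ft2)
  ref <- as.character(predict(MASS::lda(x, grouping = ft2$label))$class)
  expect_gt(mean(ours == ref), 0.98)
})

test_that("label-independent features give chance-level training accuracy", {
  withr::with_seed(12, {
    x <- matrix(rnorm(400 * 3), 400)
    ft <- feature_table(x, rep(c("baseline", "mi"), 200),
                        rep(NA_character_, 400), paste0("g", 1:400))
  })
  m <- fit_lda(ft)
  acc <- mean(predict(m, ft) == ft$label)
  expect_gte(acc, 0.4)
  expect_lte(acc, 0.7)
})

test_that("duplicated feature columns are tolerated and inert", {
  ft <- sep_features(gap = 2, seed = 4)
  x <- feature_matrix(ft)
  ft_dup <- feature_table(cbind(x, x[, 1]), ft$label, ft$speed, ft$group)
  p1 <- predict(fit_lda(ft), ft)
  p2 <- predict(fit_lda(ft_dup), ft_dup)
  expect_identical(p1, p2)
  expect_error(fit_lda(subset(ft, label == "mi")), "two classes")
})

test_that("confusion metrics follow the closed-form definitions", {
  expect_equal(confusion_metrics(list(TP = 5, TN = 5, FP = 0, FN = 0)),
               c(ACC = 1, FPR = 0))
  expect_equal(confusion_metrics(list(TP = 3, TN = 2, FP = 2, FN = 3)),
               c(ACC = 0.5, FPR = 0.5))
  # everything predicted positive on balanced classes
  expect_equal(confusion_metrics(list(TP = 10, TN = 0, FP = 10, FN = 0)),
               c(ACC = 0.5, FPR = 1))
  expect_error(confusion_metrics(list(TP = 1, TN = 0, FP = 0, FN = 0)),
               "FPR undefined")
  cnt <- confusion_counts(c("mi", "mi", "baseline"),
                          c("mi", "baseline", "mi"))
  expect_identical(c(cnt$TP, cnt$TN, cnt$FP, cnt$FN), c(1L, 0L, 1L, 1L))
})

test_that("group folds partition cleanly, stratified by class", {
  groups <- c(paste0("m", 1:30), paste0("b", 1:12))
  labels <- c(rep("mi", 30), rep("baseline", 12))
  fold <- make_group_folds(groups, labels, k = 5, seed = 3)
  expect_setequal(names(fold), groups)
  for (f in 1:5) {
    test_groups <- names(fold)[fold == f]
    expect_gte(sum(labels[match(test_groups, groups)] == "mi"), 1)
    expect_gte(sum(labels[match(test_groups, groups)] == "baseline"), 1)
  }
  expect_error(make_group_folds(groups[1:12], labels[c(1:8, 31:34)], k = 5),
               "fewer than k")
})

test_that("cross-validation is leakage-safe, deterministic, and scores windows", {
  # windows: 6 rows per group, separable classes
  n_g <- 12
  withr::with_seed(5, {
    x <- do.call(rbind, lapply(seq_len(2 * n_g), function(g) {
      center <- if (g <= n_g) 0 else 6
      matrix(rnorm(6 * 2) + center, 6)
    }))
  })
  ft <- feature_table(x,
                      rep(c("baseline", "mi"), each = 6 * n_g),
                      rep(NA_character_, 12 * n_g),
                      rep(paste0("g", seq_len(2 * n_g)), each = 6))
  res <- cross_validate(ft, k = 5, seed = 2)
  expect_equal(res$mean_acc, 1)
  expect_equal(res$mean_fpr, 0)
  # no group straddles folds: every row of a group shares one fold
  row_fold <- res$fold_of_group[ft$group]
  expect_true(all(tapply(row_fold, ft$group,
                         function(v) length(unique(v)) == 1)))
  res2 <- cross_validate(ft, k = 5, seed = 2)
  expect_identical(res$per_fold, res2$per_fold)
  res3 <- cross_validate(ft, k = 5, seed = 3)
  expect_false(identical(res$fold_of_group, res3$fold_of_group))
})

test_that("majority-vote scoring collapses windows to one decision per trial", {
  # 8 groups x 5 windows; one window per group deliberately flipped, so
  # per-window accuracy < 1 but the per-group vote is always right
  n_g <- 8L
  withr::with_seed(44, {
    x <- do.call(rbind, lapply(seq_len(2 * n_g), function(g) {
      center <- if (g <= n_g) 0 else 8
      m <- matrix(rnorm(5 * 2) + center, 5)
      m[1, ] <- m[1, ] + (if (g <= n_g) 8 else -8)   # one outlier window
      m
    }))
  })
  ft <- feature_table(x, rep(c("baseline", "mi"), each = 5 * n_g),
                      rep(NA_character_, 10 * n_g),
                      rep(paste0("g", seq_len(2 * n_g)), each = 5))
  window_level <- cross_validate(ft, k = 4, seed = 2)
  voted <- cross_validate(ft, k = 4, seed = 2, vote = TRUE)
  expect_lt(window_level$mean_acc, 1)
  expect_equal(voted$mean_acc, 1)
  expect_equal(voted$mean_fpr, 0)
  # voted folds score one decision per group
  totals <- with(voted$per_fold, tp + tn + fp + fn)
  expect_identical(as.integer(sum(totals)), 2L * n_g)
})

test_that("permuting labels over groups drops accuracy to chance", {
  n_g <- 24                      # >= 40 groups across both classes
  withr::with_seed(15, {
    x <- do.call(rbind, lapply(seq_len(2 * n_g), function(g) {
      center <- if (g <= n_g) 0 else 4
      matrix(rnorm(4 * 2) + center, 4)
    }))
    groups <- rep(paste0("g", seq_len(2 * n_g)), each = 4)
    perm <- sample(rep(c("baseline", "mi"), n_g))   # permuted over groups
  })
  ft <- feature_table(x, perm[match(groups, unique(groups))],
                      rep(NA_character_, length(groups)), groups)
  res <- cross_validate(ft, k = 5, seed = 6)
  expect_gte(res$mean_acc, 0.35)
  expect_lte(res$mean_acc, 0.65)
})
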