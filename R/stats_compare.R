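# Between-method significance analysis: assumption checks, directional
# two-sample t-tests at alpha = 0.05, and the significance-mark matrix.
#
# No multiple-testing correction is applied across the comparison cells;
# this mirrors the per-cell alpha = 0.05 analysis the study design calls
# for, and is surfaced prominently in the documentation.

SIG_MARK <- "\u2020"   # dagger: significant at alpha
NS_MARK <- "~"         # no significant difference

#' Distributional assumption checks for a method pair
#'
#' Shapiro-Wilk normality p-value per sample and a Levene test (centered at
#' the mean, i.e. the classical variance-homogeneity form) across the pair.
#' The p-values are reported alongside the t-test, not used to gate it.
#'
#' @param sample_a,sample_b Numeric vectors (one value per subject).
#' @return Named numeric: `shapiro_a`, `shapiro_b`, `levene`.
#' @export
check_assumptions <- function(sample_a, sample_b) {
  if (length(sample_a) < 3 || length(sample_b) < 3) {
    abort("assumption checks need at least 3 values per sample")
  }
  if (stats::sd(sample_a) == 0 || stats::sd(sample_b) == 0) {
    abort("constant sample: Shapiro-Wilk is undefined for zero variance")
  }
  lev <- car::leveneTest(
    y = c(sample_a, sample_b),
    group = factor(rep(c("a", "b"), c(length(sample_a), length(sample_b)))),
    center = mean)
  c(shapiro_a = stats::shapiro.test(sample_a)$p.value,
    shapiro_b = stats::shapiro.test(sample_b)$p.value,
    levene = lev$`Pr(>F)`[1])
}

#' Directional two-sample comparison of two methods
#'
#' One-sided pooled-variance two-sample t-test of per-subject metric values.
#' `sample_a` is the method hypothesized better: for ACC the alternative is
#' `mean(a) > mean(b)`, for FPR (where lower is better) `mean(a) < mean(b)`.
#'
#' @param sample_a,sample_b Per-subject metric values; `a` is the method
#'   hypothesized better.
#' @param metric `"ACC"` or `"FPR"` (sets the direction of the alternative).
#' @param alpha Significance threshold.
#' @param check Also run [check_assumptions()] and attach its p-values.
#' @return A `comparison_cell`: `t_statistic`, `df`, `p_value`,
#'   `significant`, `direction`, `assumption_p` (or NULL).
#' @export
compare_methods <- function(sample_a, sample_b, metric = c("ACC", "FPR"),
                            alpha = 0.05, check = TRUE) {
  metric <- match.arg(metric)
  if (length(sample_a) < 2 || length(sample_b) < 2) {
    abort("need at least two values per sample")
  }
  alternative <- if (metric == "ACC") "greater" else "less"
  na <- length(sample_a)
  nb <- length(sample_b)
  df <- na + nb - 2
  sp2 <- ((na - 1) * stats::var(sample_a) + (nb - 1) * stats::var(sample_b)) / df
  delta <- mean(sample_a) - mean(sample_b)
  if (sp2 > 0) {
    tstat <- delta / sqrt(sp2 * (1 / na + 1 / nb))
  } else {
    # both samples constant: equal means are a null result, unequal means an
    # infinitely strong one
    tstat <- if (delta == 0) 0 else sign(delta) * Inf
  }
  p <- if (alternative == "greater") stats::pt(tstat, df, lower.tail = FALSE)
       else stats::pt(tstat, df)
  assum <- if (check) tryCatch(check_assumptions(sample_a, sample_b),
                               error = function(e) NULL) else NULL
  structure(list(t_statistic = tstat,
                 df = df,
                 p_value = p,
                 significant = p < alpha,
                 alpha = alpha,
                 direction = sprintf("mean(a) %s mean(b)",
                                     if (alternative == "greater") ">" else "<"),
                 metric = metric,
                 assumption_p = assum),
            class = "comparison_cell")
}

#' @export
print.comparison_cell <- function(x, ...) {
  cat(sprintf("<comparison_cell> %s: t = %.3f (df %g), one-sided p = %.4g %s\n",
              x$metric, x$t_statistic, x$df, x$p_value,
              if (x$significant) SIG_MARK else NS_MARK))
  invisible(x)
}

# method pairs compared, first member hypothesized better
method_pairs <- function() {
  list(c("csp", "fbcsp"), c("csp", "fbcssp"), c("fbcsp", "fbcssp"))
}

#' Build the between-method significance table
#'
#' Runs [compare_methods()] for every method pair (CSP vs FBCSP, CSP vs
#' FBCSSP, FBCSP vs FBCSSP) in every condition cell (session x segmentation
#' x metric x speed) of a study evaluation table, using per-subject
#' fold-mean metric values as the samples.
#'
#' @param eval_rows Flat evaluation table as produced by [run_study()]: one
#'   row per subject x session x method x segmentation x speed x fold with
#'   `acc` and `fpr` columns.
#' @param alpha Significance threshold.
#' @return Data frame (class `significance_table`): one row per comparison
#'   cell with `session`, `segmentation`, `metric`, `speed`, `method_a`,
#'   `method_b`, `t`, `df`, `p`, `significant`, `mark`, and the assumption
#'   p-values.
#' @export
build_significance_table <- function(eval_rows, alpha = 0.05) {
  need <- c("subject", "session", "method", "segmentation", "speed",
            "fold", "acc", "fpr")
  missing_cols <- setdiff(need, names(eval_rows))
  if (length(missing_cols)) {
    abort("eval table is missing columns: %s",
          paste(missing_cols, collapse = ", "))
  }
  # per-subject mean over folds
  agg <- stats::aggregate(cbind(acc, fpr) ~ subject + session + method +
                            segmentation + speed, data = eval_rows, FUN = mean)
  pairs <- Filter(function(p) all(p %in% unique(agg$method)), method_pairs())
  if (length(pairs) == 0) {
    abort("significance table needs at least two of csp/fbcsp/fbcssp")
  }
  cells <- expand.grid(session = sort(unique(agg$session)),
                       segmentation = sort(unique(agg$segmentation)),
                       metric = c("ACC", "FPR"),
                       speed = sort(unique(agg$speed)),
                       pair = seq_along(pairs),
                       stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(cells)), function(i) {
    cc <- cells[i, ]
    pr <- pairs[[cc$pair]]
    col <- tolower(cc$metric)
    pick <- function(m) {
      s <- agg[agg$session == cc$session & agg$segmentation == cc$segmentation &
                 agg$speed == cc$speed & agg$method == m, ]
      s <- s[order(s$subject), ]
      s[[col]]
    }
    a <- pick(pr[1])
    b <- pick(pr[2])
    if (length(a) == 0 || length(b) == 0) {
      abort("missing condition: session %s, %s, %s, speed %s, method %s",
            cc$session, cc$segmentation, cc$metric, cc$speed,
            pr[which(c(length(a), length(b)) == 0)[1]])
    }
    cell <- compare_methods(a, b, metric = cc$metric, alpha = alpha)
    data.frame(session = cc$session, segmentation = cc$segmentation,
               metric = cc$metric, speed = cc$speed,
               method_a = pr[1], method_b = pr[2],
               t = cell$t_statistic, df = cell$df, p = cell$p_value,
               significant = cell$significant,
               mark = if (cell$significant) SIG_MARK else NS_MARK,
               shapiro_a = cell$assumption_p[["shapiro_a"]] %||% NA_real_,
               shapiro_b = cell$assumption_p[["shapiro_b"]] %||% NA_real_,
               levene = cell$assumption_p[["levene"]] %||% NA_real_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("significance_table", "data.frame")
  out
}

#' Render one session's significance marks as a compact matrix
#'
#' Rows are method pairs; columns are segmentation x metric x speed
#' (`TW0/ACC-H ... TW3/FPR-L`), each cell the dagger/tilde mark.
#'
#' @param sig A [build_significance_table()] result.
#' @param session Session id to render.
#' @export
render_significance_matrix <- function(sig, session) {
  s <- sig[sig$session == session, , drop = FALSE]
  if (nrow(s) == 0) abort("no comparison cells for session %s", session)
  s$speed_tag <- ifelse(s$speed == "high", "H", "L")
  s$col <- sprintf("%s/%s-%s", toupper(s$segmentation), s$metric, s$speed_tag)
  s$row <- sprintf("%s vs %s", toupper(s$method_a), toupper(s$method_b))
  cols <- sort(unique(s$col))
  rows <- unique(s$row)
  m <- matrix(NA_character_, length(rows), length(cols),
              dimnames = list(rows, cols))
  for (i in seq_len(nrow(s))) m[s$row[i], s$col[i]] <- s$mark[i]
  m
}
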