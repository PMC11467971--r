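# Common Spatial Patterns: covariance estimation, the generalized
# eigenproblem, projection, and log-variance features.
#
# For class covariances Ca, Cb the spatial filters w solve
#   Ca w = lambda (Ca + Cb) w,
# i.e. each filter's eigenvalue is the share of class-a variance in the
# composite; lambda near 1 (or 0) marks a direction where class a has much
# more (or much less) variance than class b. The filter matrix W
# simultaneously diagonalizes both covariances with W (Ca + Cb) W' = I.

#' Average trace-normalized class covariance
#'
#' Per trial, the channel covariance `Y Y' / trace(Y Y')` (so every trial
#' contributes with unit total power regardless of amplitude), averaged with
#' equal weight over the trials carrying `label`.
#'
#' @param trials A [trial_set()].
#' @param label Class label to average over.
#' @param normalization `"trace"` (default) or `"none"`.
#' @return An object of class `cov_estimate` with fields `matrix`,
#'   `n_trials_averaged`, `normalization`.
#' @export
class_covariance <- function(trials, label, normalization = c("trace", "none")) {
  normalization <- match.arg(normalization)
  idx <- which(trials$labels == label)
  if (length(idx) == 0) abort("no trials with label '%s'", label)
  C <- dim(trials$trials)[2]
  acc <- matrix(0, C, C)
  for (i in idx) {
    y <- get_trial(trials, i)
    cc <- tcrossprod(y)
    tr <- sum(diag(cc))
    if (tr <= 0) abort("trial %d (group %s) has zero variance", i,
                       trials$groups[i])
    if (normalization == "trace") cc <- cc / tr
    acc <- acc + cc
  }
  structure(list(matrix = acc / length(idx),
                 n_trials_averaged = length(idx),
                 normalization = normalization),
            class = "cov_estimate")
}

as_cov_matrix <- function(x) {
  if (inherits(x, "cov_estimate")) x$matrix else as.matrix(x)
}

#' Fit a CSP spatial filter
#'
#' Solves the generalized eigenproblem on the two class covariances and keeps
#' the `n_pairs` most class-a-dominant and `n_pairs` most class-b-dominant
#' filters. Each filter is scaled so `w' (Ca + Cb) w = 1` and its
#' largest-magnitude coefficient is made positive (the sign is mathematically
#' free). A tiny ridge (`1e-9 * trace/C` on the diagonal of each covariance)
#' guards against rank deficiency from short windows.
#'
#' @param cov_a,cov_b Class covariances (`cov_estimate` or plain matrices) of
#'   equal size.
#' @param n_pairs Filter pairs to retain; the model has `2 * n_pairs` filters.
#' @param class_order Length-2 character naming classes (a, b); stored only.
#' @param ridge Relative ridge added to each covariance diagonal.
#' @return An object of class `csp_model`: `weights` (`P x C`, filters in
#'   rows), `eigenvalues` (class-a variance share per filter, first `n_pairs`
#'   descending from the top of the spectrum, last `n_pairs` ascending from
#'   the bottom), `n_pairs`, `class_order`.
#' @export
fit_csp <- function(cov_a, cov_b, n_pairs = 3,
                    class_order = c("a", "b"), ridge = 1e-9) {
  ca <- as_cov_matrix(cov_a)
  cb <- as_cov_matrix(cov_b)
  if (!all(dim(ca) == dim(cb))) abort("class covariances differ in size")
  C <- nrow(ca)
  if (2 * n_pairs > C) {
    abort("2 * n_pairs = %d exceeds the %d available channels", 2 * n_pairs, C)
  }
  ca <- ca + diag(ridge * sum(diag(ca)) / C, C)
  cb <- cb + diag(ridge * sum(diag(cb)) / C, C)
  comp <- ca + cb
  ec <- eigen(comp, symmetric = TRUE)
  if (min(ec$values) <= 0) {
    abort("composite covariance is not positive definite even after ridge")
  }
  # whiten the composite, then diagonalize class a in whitened space
  wh <- diag(1 / sqrt(ec$values)) %*% t(ec$vectors)
  s <- wh %*% ca %*% t(wh)
  es <- eigen((s + t(s)) / 2, symmetric = TRUE)   # values descending
  w_full <- t(es$vectors) %*% wh                  # rows: filters, desc lambda
  lam <- es$values
  sel <- c(seq_len(n_pairs), C - seq_len(n_pairs) + 1L)  # top desc, bottom asc
  w <- w_full[sel, , drop = FALSE]
  lam <- lam[sel]
  # sign convention: largest-magnitude coefficient positive
  for (i in seq_len(nrow(w))) {
    j <- which.max(abs(w[i, ]))
    if (w[i, j] < 0) w[i, ] <- -w[i, ]
  }
  colnames(w) <- colnames(ca)
  structure(list(weights = w,
                 eigenvalues = pmin(pmax(lam, 0), 1),
                 n_pairs = as.integer(n_pairs),
                 class_order = class_order),
            class = "csp_model")
}

#' Project a trial through a spatial filter
#'
#' Computes the surrogate signals `W Y` (filters in rows of `W`, channels in
#' rows of `Y`), shape `P x t`.
#'
#' @param model A `csp_model`.
#' @param trial Channel-by-sample numeric matrix.
#' @export
apply_spatial_filter <- function(model, trial) {
  if (ncol(model$weights) != nrow(trial)) {
    abort("trial has %d channels but the model expects %d",
          nrow(trial), ncol(model$weights))
  }
  model$weights %*% trial
}

#' Log-variance features of projected signals
#'
#' The standard CSP feature: `log(var_p / sum_q var_q)` over the projected
#' components (scale-invariant); `normalize = FALSE` gives plain `log(var_p)`.
#'
#' @param projected `P x t` matrix of projected signals (components in rows).
#' @param normalize Divide by the total variance before the log.
#' @export
log_variance_features <- function(projected, normalize = TRUE) {
  v <- row_vars(projected)
  if (any(v <= 0)) abort("zero-variance projected component")
  if (normalize) log(v / sum(v)) else log(v)
}

#' @export
print.csp_model <- function(x, ...) {
  cat(sprintf("<csp_model> %d filters over %d channels | lambda: %s\n",
              nrow(x$weights), ncol(x$weights),
              paste(sprintf("%.3f", x$eigenvalues), collapse = " ")))
  invisible(x)
}
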