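# Internal helpers shared across modules.

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so library code never clobbers the
#' caller's random stream.
#' @noRd
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Derive a child seed from a base seed and integer coordinates
#'
#' Deterministic, order-sensitive fold of the coordinates into [1, 2^31 - 2].
#' @noRd
derive_seed <- function(base, ...) {
  m <- 2147483629          # prime below 2^31
  x <- as.numeric(base) %% m
  for (k in c(...)) {
    x <- (x * 69069 + as.numeric(k) * 104729 + 12345) %% m
  }
  as.integer(x + 1)
}

#' Moore-Penrose pseudoinverse of a full-column-rank matrix
#' @noRd
pinv_full <- function(m) {
  solve(crossprod(m), t(m))
}

#' Stop with a formatted message
#' @noRd
abort <- function(...) stop(sprintf(...), call. = FALSE)

is_scalar_num <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

#' Row variances of a matrix (components in rows, samples in columns)
#' @noRd
row_vars <- function(m) {
  mu <- rowMeans(m)
  rowSums((m - mu)^2) / (ncol(m) - 1)
}
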