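# Epoched-trial container used by every stage downstream of epoching.

#' Construct a set of epoched trials
#'
#' @param trials 3-D array, `trial x channel x sample`.
#' @param labels Character class per trial, `"baseline"` or `"mi"`.
#' @param speeds Character per trial: `"low"`, `"high"`, or `NA` for
#'   baseline pseudo-trials.
#' @param groups Source-trial id per trial; windows cut from one trial share
#'   its group id, which is what makes grouped cross-validation leakage-safe.
#' @param sampling_rate Hz.
#' @param session_id,subject_id Provenance.
#' @param channel_labels Electrode names (length = channel dimension).
#' @return An object of class `trial_set`.
#' @export
trial_set <- function(trials, labels, speeds, groups, sampling_rate,
                      session_id = NA, subject_id = NA,
                      channel_labels = NULL) {
  if (length(dim(trials)) != 3L) {
    abort("trials must be a 3-D array (trial x channel x sample)")
  }
  n <- dim(trials)[1]
  if (length(labels) != n || length(speeds) != n || length(groups) != n) {
    abort("labels, speeds and groups must each have one entry per trial")
  }
  structure(list(
    trials = trials,
    labels = as.character(labels),
    speeds = as.character(speeds),
    groups = as.character(groups),
    sampling_rate = sampling_rate,
    session_id = session_id,
    subject_id = subject_id,
    channel_labels = channel_labels
  ), class = "trial_set")
}

#' Number of trials in a trial set
#' @param ts A [trial_set()].
#' @export
n_trials <- function(ts) dim(ts$trials)[1]

#' Extract one trial as a channel-by-sample matrix
#' @param ts A [trial_set()].
#' @param i Trial index.
#' @export
get_trial <- function(ts, i) {
  m <- ts$trials[i, , , drop = TRUE]
  dim(m) <- dim(ts$trials)[2:3]
  m
}

#' Subset a trial set by trial index
#' @param ts A [trial_set()].
#' @param idx Integer or logical index over trials.
#' @export
subset_trials <- function(ts, idx) {
  trial_set(ts$trials[idx, , , drop = FALSE],
            ts$labels[idx], ts$speeds[idx], ts$groups[idx],
            ts$sampling_rate, ts$session_id, ts$subject_id,
            ts$channel_labels)
}

#' Concatenate trial sets with identical channel/sample geometry
#' @param ... [trial_set()] objects.
#' @export
bind_trial_sets <- function(...) {
  sets <- list(...)
  dims <- vapply(sets, function(s) dim(s$trials)[2:3], numeric(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
    abort("cannot bind trial sets with differing channel or sample counts")
  }
  arr <- do.call(abind3, lapply(sets, `[[`, "trials"))
  trial_set(arr,
            unlist(lapply(sets, `[[`, "labels")),
            unlist(lapply(sets, `[[`, "speeds")),
            unlist(lapply(sets, `[[`, "groups")),
            sets[[1]]$sampling_rate, sets[[1]]$session_id,
            sets[[1]]$subject_id, sets[[1]]$channel_labels)
}

# bind 3-D arrays along the first margin
abind3 <- function(...) {
  arrs <- list(...)
  d <- dim(arrs[[1]])[2:3]
  n <- sum(vapply(arrs, function(a) dim(a)[1], numeric(1)))
  out <- array(NA_real_, c(n, d))
  at <- 0L
  for (a in arrs) {
    k <- dim(a)[1]
    if (k > 0) out[at + seq_len(k), , ] <- a
    at <- at + k
  }
  out
}

#' @export
print.trial_set <- function(x, ...) {
  d <- dim(x$trials)
  cat(sprintf(
    "<trial_set> %d trials x %d ch x %d samples @ %g Hz | classes: %s\n",
    d[1], d[2], d[3], x$sampling_rate,
    paste(sprintf("%s=%d", names(table(x$labels)), table(x$labels)),
          collapse = ", ")))
  invisible(x)
}
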