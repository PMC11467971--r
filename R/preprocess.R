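# Band-pass filtering, epoching, and temporal segmentation.

#' Describe a band-pass filter
#'
#' @param low_hz,high_hz Band edges in Hz, `0 < low < high < Nyquist`.
#' @param order Butterworth order of the analog prototype (the band-pass IIR
#'   has twice this order); applied forward-backward the effective magnitude
#'   response is squared.
#' @export
band_spec <- function(low_hz, high_hz, order = 5) {
  if (!is_scalar_num(low_hz) || !is_scalar_num(high_hz) ||
      low_hz <= 0 || high_hz <= low_hz) {
    abort("invalid band: need 0 < low_hz < high_hz")
  }
  structure(list(low_hz = low_hz, high_hz = high_hz, order = as.integer(order)),
            class = "band_spec")
}

#' The broadband sensorimotor band used for single-layer CSP
#' @export
mu_beta_band <- function() band_spec(8, 30, order = 5)

# Design the digital band-pass for a given sampling rate.
design_butter <- function(band, fs) {
  nyq <- fs / 2
  if (band$high_hz >= nyq) {
    abort("band edge %g Hz at or above Nyquist (%g Hz)", band$high_hz, nyq)
  }
  signal::butter(band$order, c(band$low_hz, band$high_hz) / nyq, type = "pass")
}

# Zero-phase filtering of one numeric vector with even-extension padding.
# Pad length follows the 3 * filter-length convention, capped at n - 1.
filtfilt_even <- function(flt, x) {
  n <- length(x)
  pad <- min(3L * max(length(flt$b), length(flt$a)), n - 1L)
  xp <- c(x[(pad + 1):2], x, x[(n - 1):(n - pad)])
  y <- signal::filter(flt, xp)
  y <- rev(signal::filter(flt, rev(y)))
  as.numeric(y[(pad + 1):(pad + n)])
}

#' Zero-phase Butterworth band-pass filtering
#'
#' Applies the designed band-pass forward and backward (zero net phase,
#' squared magnitude response) independently per channel, with even-extension
#' padding at both ends to suppress edge transients.
#'
#' @param x A `recording`, `trial_set`, or channel-by-sample numeric matrix.
#' @param band A [band_spec()].
#' @param sampling_rate Hz; required only for the matrix method.
#' @return Same shape and class as the input, filtered.
#' @export
bandpass_zero_phase <- function(x, band, sampling_rate = NULL) {
  UseMethod("bandpass_zero_phase")
}

#' @export
bandpass_zero_phase.matrix <- function(x, band, sampling_rate = NULL) {
  if (is.null(sampling_rate)) abort("sampling_rate required for matrix input")
  if (ncol(x) <= 3L * band$order) {
    abort("signal too short to filter: %d samples for order %d",
          ncol(x), band$order)
  }
  flt <- design_butter(band, sampling_rate)
  t(apply(x, 1, function(ch) filtfilt_even(flt, ch)))
}

#' @export
bandpass_zero_phase.recording <- function(x, band, sampling_rate = NULL) {
  x$data <- bandpass_zero_phase.matrix(x$data, band, x$sampling_rate)
  x
}

#' @export
bandpass_zero_phase.trial_set <- function(x, band, sampling_rate = NULL) {
  if (dim(x$trials)[3] <= 3L * band$order) {
    abort("trials too short to filter: %d samples for order %d",
          dim(x$trials)[3], band$order)
  }
  flt <- design_butter(band, x$sampling_rate)
  for (i in seq_len(n_trials(x))) {
    x$trials[i, , ] <- t(apply(get_trial(x, i), 1,
                               function(ch) filtfilt_even(flt, ch)))
  }
  x
}

#' Analytic squared-magnitude response of the zero-phase band-pass
#'
#' @param band A [band_spec()].
#' @param freq_hz Frequencies at which to evaluate.
#' @param sampling_rate Hz.
#' @return Power gain (|H|^2, i.e. the forward-backward amplitude gain) at
#'   each frequency.
#' @export
bandpass_response <- function(band, freq_hz, sampling_rate) {
  flt <- design_butter(band, sampling_rate)
  w <- 2 * pi * freq_hz / sampling_rate
  h <- vapply(w, function(wi) {
    z <- exp(-1i * wi * (seq_along(flt$b) - 1))
    Mod(sum(flt$b * z) / sum(flt$a * z))
  }, numeric(1))
  h^2
}

#' Epoch the MI+passive trials of a recording
#'
#' One epoch per MI marker, spanning the full MI phase from its onset; the
#' speed label and trial index are carried from the marker.
#'
#' @param recording A `recording` (see [generate_session()]).
#' @return A [trial_set()] with class `"mi"` and groups `"mi<trial>"`.
#' @export
epoch_mi_trials <- function(recording) {
  fs <- recording$sampling_rate
  len <- round((recording$mi_duration %||% 10) * fs)
  mk <- recording$markers[recording$markers$phase == "mi", , drop = FALSE]
  C <- nrow(recording$data)
  N <- ncol(recording$data)
  if (nrow(mk) == 0) {
    return(trial_set(array(numeric(0), c(0, C, len)), character(0),
                     character(0), character(0), fs,
                     recording$session_id, recording$subject_id,
                     recording$channel_labels))
  }
  arr <- array(NA_real_, c(nrow(mk), C, len))
  for (i in seq_len(nrow(mk))) {
    a <- mk$onset[i] + 1L              # onsets are 0-based
    b <- mk$onset[i] + len
    if (b > N) {
      abort("MI trial %d extends past the end of the recording", mk$trial[i])
    }
    arr[i, , ] <- recording$data[, a:b]
  }
  trial_set(arr, rep("mi", nrow(mk)), mk$speed,
            paste0("mi", mk$trial), fs,
            recording$session_id, recording$subject_id,
            recording$channel_labels)
}

#' Cut the baseline segment into pseudo-trials
#'
#' The continuous passive-movement baseline is split into consecutive
#' non-overlapping pseudo-trials so the baseline class enters classification
#' with the same trial geometry as the MI class. Each pseudo-trial gets a
#' unique group id; the speed is `NA` (the baseline runs at the low speed by
#' protocol, but carries no speed contrast).
#'
#' @param recording A `recording`.
#' @param pseudo_trial_s Pseudo-trial length in seconds.
#' @export
epoch_baseline <- function(recording, pseudo_trial_s = 10) {
  fs <- recording$sampling_rate
  mk <- recording$markers
  b0 <- mk$onset[mk$phase == "baseline"]
  if (length(b0) != 1) abort("recording has no baseline marker")
  nxt <- mk$onset[mk$onset > b0]
  b_end <- if (length(nxt)) min(nxt) else ncol(recording$data)
  base_len <- b_end - b0
  w <- round(pseudo_trial_s * fs)
  if (w > base_len) {
    abort("pseudo_trial_s (%g s) exceeds the baseline duration (%g s)",
          pseudo_trial_s, base_len / fs)
  }
  k <- floor(base_len / w)
  C <- nrow(recording$data)
  arr <- array(NA_real_, c(k, C, w))
  for (i in seq_len(k)) {
    a <- b0 + (i - 1L) * w + 1L
    arr[i, , ] <- recording$data[, a:(a + w - 1L)]
  }
  trial_set(arr, rep("baseline", k), rep(NA_character_, k),
            paste0("base", seq_len(k)), fs,
            recording$session_id, recording$subject_id,
            recording$channel_labels)
}

#' Sliding-window temporal segmentation (dynamic, "TW0")
#'
#' Tiles each trial with windows of `window_s` seconds overlapped by
#' `overlap`, starting at sample 0 and keeping only windows fully inside the
#' trial. The hop is `floor(w * (1 - overlap))` samples. Every window
#' inherits its parent trial's label, speed, and group id, so grouped
#' cross-validation never splits a trial across folds.
#'
#' @param trials A [trial_set()].
#' @param window_s Window length, seconds.
#' @param overlap Fractional overlap in `[0, 1)`.
#' @export
segment_tw0 <- function(trials, window_s = 1.0, overlap = 0.5) {
  fs <- trials$sampling_rate
  len <- dim(trials$trials)[3]
  w <- round(window_s * fs)
  if (overlap < 0 || overlap >= 1) abort("overlap must lie in [0, 1)")
  if (w > len) {
    abort("window (%d samples) longer than trial (%d samples)", w, len)
  }
  hop <- max(1L, floor(w * (1 - overlap)))
  starts <- seq.int(0L, len - w, by = hop)
  nw <- length(starts)
  n <- n_trials(trials)
  C <- dim(trials$trials)[2]
  arr <- array(NA_real_, c(n * nw, C, w))
  for (i in seq_len(n)) {
    for (j in seq_len(nw)) {
      arr[(i - 1L) * nw + j, , ] <-
        trials$trials[i, , (starts[j] + 1L):(starts[j] + w)]
    }
  }
  rep_i <- rep(seq_len(n), each = nw)
  trial_set(arr, trials$labels[rep_i], trials$speeds[rep_i],
            trials$groups[rep_i], fs, trials$session_id,
            trials$subject_id, trials$channel_labels)
}

#' Static temporal crop (static, "TW3")
#'
#' Keeps one fixed interval per trial, `[start_s, end_s)` relative to trial
#' onset, half-open in samples.
#'
#' @param trials A [trial_set()].
#' @param start_s,end_s Crop interval in seconds from trial onset.
#' @export
segment_tw3 <- function(trials, start_s = 1.0, end_s = 6.0) {
  fs <- trials$sampling_rate
  len <- dim(trials$trials)[3]
  a <- round(start_s * fs)
  b <- round(end_s * fs)
  if (start_s < 0 || start_s >= end_s || b > len) {
    abort("crop [%g, %g) s is out of range for %g-s trials",
          start_s, end_s, len / fs)
  }
  out <- trials
  out$trials <- trials$trials[, , (a + 1L):b, drop = FALSE]
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
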