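# Protocol-faithful synthetic EEG with known ground truth.
#
# Sources are band-limited Gaussian oscillations over a 1/f background,
# mixed into channels by the ground-truth gain matrix plus white sensor
# noise. The class effect is a multiplicative band-power attenuation (ERD)
# of one source during MI+passive phases.

# 1/f-amplitude ("pink") noise, unit variance, via FFT spectral shaping.
# Generated at a 2-3-5-smooth length (fast mixed-radix FFT) and truncated.
pink_noise <- function(n) {
  m <- stats::nextn(n, c(2, 3, 5))
  w <- stats::rnorm(m)
  W <- stats::fft(w)
  k <- 0:(m - 1)
  f <- pmin(k, m - k)          # symmetric frequency index
  scale <- 1 / sqrt(pmax(f, 1))
  scale[1] <- 0                # drop DC
  x <- Re(stats::fft(W * scale, inverse = TRUE))[seq_len(n)] / m
  x / stats::sd(x)
}

# One latent source: unit-variance band-limited Gaussian + 1/f background.
make_source <- function(n, band_hz, fs, onef_sd) {
  raw <- stats::rnorm(n)
  flt <- design_butter(band_spec(band_hz[1], band_hz[2], order = 4), fs)
  osc <- filtfilt_even(flt, raw)
  osc <- osc / stats::sd(osc)
  bg <- if (onef_sd > 0) onef_sd * pink_noise(n) else 0
  osc + bg
}

#' Generate one synthetic recording session
#'
#' Produces a continuous multichannel recording following the acquisition
#' protocol: a passive-movement baseline, then `trials_per_session` trials
#' each running beep -> no-action (duration drawn uniformly from
#' `no_action_range`) -> MI+passive movement. The speed sequence is a seeded
#' random permutation of `trials_per_speed` low- plus `trials_per_speed`
#' high-speed trials. During MI phases the discriminative source's amplitude
#' is multiplied by `sqrt(erd_attenuation[speed])`.
#'
#' @param spec A [protocol_spec()].
#' @param truth A [ground_truth()].
#' @param session_id,subject_id Integers recorded in the output.
#' @param seed Seed for this session; defaults to a value derived from
#'   `truth$seed` and the ids, so sessions of one truth differ but rerunning
#'   is bit-identical.
#' @return A `recording`: list with `data` (channel x sample matrix,
#'   microvolts), `sampling_rate`, `channel_labels`, `markers` (data frame
#'   with 0-based `onset`, `phase`, `speed`, `trial`), `mi_duration`,
#'   `session_id`, `subject_id`.
#' @export
generate_session <- function(spec, truth, session_id = 1L, subject_id = 1L,
                             seed = NULL) {
  validate_protocol_spec(spec)
  validate_ground_truth(truth)
  if (nrow(truth$mixing) != spec$n_channels) {
    abort("mixing has %d rows but the protocol has %d channels",
          nrow(truth$mixing), spec$n_channels)
  }
  if (is.null(seed)) seed <- derive_seed(truth$seed, subject_id, session_id)
  fs <- spec$sampling_rate
  with_seed(seed, {
    nb <- round(spec$baseline_duration * fs)
    n_beep <- round(spec$beep_duration * fs)
    n_mi <- round(spec$mi_duration * fs)
    nt <- spec$trials_per_session
    n_noact <- round(stats::runif(nt, spec$no_action_range[1],
                                  spec$no_action_range[2]) * fs)
    speed_seq <- sample(rep(names(spec$speeds), each = spec$trials_per_speed))

    # timeline
    markers <- data.frame(onset = 0L, phase = "baseline",
                          speed = NA_character_, trial = NA_integer_,
                          stringsAsFactors = FALSE)
    pos <- nb
    for (t in seq_len(nt)) {
      markers <- rbind(markers,
        data.frame(onset = c(pos, pos + n_beep, pos + n_beep + n_noact[t]),
                   phase = c("beep", "no_action", "mi"),
                   speed = speed_seq[t], trial = t,
                   stringsAsFactors = FALSE))
      pos <- pos + n_beep + n_noact[t] + n_mi
    }
    N <- pos
    markers$onset <- as.integer(markers$onset)
    markers$trial <- as.integer(markers$trial)

    # sources
    S <- ncol(truth$mixing)
    src <- matrix(NA_real_, S, N)
    for (s in seq_len(S)) {
      src[s, ] <- make_source(N, truth$source_bands[[s]], fs, truth$onef_sd)
    }

    # trial-to-trial gain jitter on nuisance sources (piecewise-constant)
    if (truth$gain_jitter_sd > 0) {
      blk <- max(1L, round(truth$gain_block_s * fs))
      nblk <- ceiling(N / blk)
      for (s in setdiff(seq_len(S), truth$discriminative_source_index)) {
        g <- exp(stats::rnorm(nblk, 0, truth$gain_jitter_sd))
        src[s, ] <- src[s, ] * rep(g, each = blk)[seq_len(N)]
      }
    }

    # ERD: attenuate the discriminative source during MI phases
    mi_rows <- which(markers$phase == "mi")
    for (i in mi_rows) {
      a <- markers$onset[i] + 1L
      b <- markers$onset[i] + n_mi
      att <- truth$erd_attenuation[[markers$speed[i]]]
      src[truth$discriminative_source_index, a:b] <-
        src[truth$discriminative_source_index, a:b] * sqrt(att)
    }

    data <- truth$mixing %*% src
    if (truth$noise_sd > 0) {
      data <- data + matrix(stats::rnorm(length(data), 0, truth$noise_sd),
                            nrow(data), ncol(data))
    }
    rownames(data) <- spec$channel_labels

    structure(list(
      data = data,
      sampling_rate = fs,
      channel_labels = spec$channel_labels,
      markers = markers,
      mi_duration = spec$mi_duration,
      session_id = session_id,
      subject_id = subject_id,
      seed = seed
    ), class = "recording")
  })
}

#' Generate a multi-subject cohort
#'
#' Each subject receives an independent small seeded rotation of the template
#' mixing matrix (inter-subject spatial variability) and
#' `spec$sessions_per_subject` sessions with seeds derived from `base_seed`.
#'
#' @param spec A [protocol_spec()].
#' @param truth_template A [ground_truth()] shared across subjects.
#' @param n_subjects Number of subjects.
#' @param base_seed Master seed; everything else derives from it.
#' @param rotation_sd Scale of the per-subject mixing rotation (radians).
#' @return List of subjects; each element holds `subject_id`, the subject's
#'   `truth`, and `sessions`, a list of recordings.
#' @export
generate_cohort <- function(spec, truth_template, n_subjects = 10,
                            base_seed = 1L, rotation_sd = 0.05) {
  if (n_subjects < 1) abort("n_subjects must be >= 1")
  lapply(seq_len(n_subjects), function(subj) {
    truth_s <- truth_template
    truth_s$mixing <- with_seed(derive_seed(base_seed, subj, 0L), {
      rotate_columns(truth_template$mixing, rotation_sd)
    })
    truth_s$seed <- derive_seed(base_seed, subj)
    sessions <- lapply(seq_len(spec$sessions_per_subject), function(sess) {
      generate_session(spec, truth_s, session_id = sess, subject_id = subj,
                       seed = derive_seed(base_seed, subj, sess))
    })
    list(subject_id = subj, truth = truth_s, sessions = sessions)
  })
}

# Exact orthogonal rotation via the Cayley transform of a small
# skew-symmetric matrix; preserves column rank and norms.
rotate_columns <- function(mixing, sd) {
  C <- nrow(mixing)
  a <- matrix(stats::rnorm(C * C, 0, sd), C, C)
  s <- (a - t(a)) / 2
  r <- solve(diag(C) - s / 2, diag(C) + s / 2)
  r %*% mixing
}

#' Measure the realized ERD of the planted source
#'
#' Generator self-check: recovers the latent sources through the known
#' mixing (pseudoinverse), band-passes the discriminative source to its own
#' band, and compares its mean power in MI phases against the baseline
#' segment, per speed. With the configured attenuation `r`, the realized
#' ratio should be close to `r`.
#'
#' @param recording Output of [generate_session()].
#' @param truth The [ground_truth()] used to generate it.
#' @param spec The matching [protocol_spec()].
#' @return Named numeric, realized MI/baseline band-power ratio per speed.
#' @export
measure_ground_truth_erd <- function(recording, truth, spec) {
  fs <- recording$sampling_rate
  mk <- recording$markers
  if (!any(mk$phase == "baseline") || !any(mk$phase == "mi")) {
    abort("recording is missing baseline or MI phases")
  }
  src_hat <- pinv_full(truth$mixing) %*% recording$data
  di <- truth$discriminative_source_index
  band <- truth$source_bands[[di]]
  x <- filtfilt_even(design_butter(band_spec(band[1], band[2], order = 4), fs),
                     src_hat[di, ])
  nb <- round(spec$baseline_duration * fs)
  n_mi <- round(spec$mi_duration * fs)
  p_base <- mean(x[seq_len(nb)]^2)
  mi_mk <- mk[mk$phase == "mi", , drop = FALSE]
  out <- vapply(names(spec$speeds), function(sp) {
    rows <- which(mi_mk$speed == sp)
    p <- vapply(rows, function(i) {
      a <- mi_mk$onset[i] + 1L
      mean(x[a:(a + n_mi - 1L)]^2)
    }, numeric(1))
    mean(p) / p_base
  }, numeric(1))
  names(out) <- names(spec$speeds)
  out
}

#' @export
print.recording <- function(x, ...) {
  cat(sprintf(
    "<recording> subject %s session %s | %d ch x %d samples @ %g Hz (%.1f s) | %d MI trials\n",
    x$subject_id, x$session_id, nrow(x$data), ncol(x$data), x$sampling_rate,
    ncol(x$data) / x$sampling_rate, sum(x$markers$phase == "mi")))
  invisible(x)
}
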