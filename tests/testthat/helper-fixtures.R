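# Small, fast fixtures built in code.

# reduced protocol: 8 channels, 40-s baseline, 6 trials (3 per speed)
mini_spec <- function() {
  protocol_spec(baseline_duration = 40, trials_per_session = 6,
                trials_per_speed = 3,
                channel_labels = paste0("ch", 1:8))
}

# matching ground truth: 4 sources into 8 channels
mini_truth <- function(att = c(low = 0.4, high = 0.35), noise_sd = 0.3,
                       jitter = 0.1, seed = 1L) {
  mixing <- withr::with_seed(11, {
    qr.Q(qr(matrix(rnorm(8 * 4), 8, 4))) * 2
  })
  ground_truth(mixing = mixing,
               source_bands = list(c(8, 12), c(15, 22), c(9, 13), c(22, 30)),
               discriminative_source_index = 1L,
               erd_attenuation = att, noise_sd = noise_sd,
               gain_jitter_sd = jitter, seed = seed)
}

# a study config over the reduced protocol (3 folds: only 3 MI groups/speed)
mini_config <- function(..., seed = 1L) {
  spec <- mini_spec()
  study_config(protocol = spec, truth = mini_truth(), k_folds = 3,
               n_subjects = 2, seed = seed, ...)
}

# trial set with per-trial channel data drawn from given per-class
# covariance matrices (long trials so sample covariances are close)
toy_trial_set <- function(cov_a, cov_b, n_per_class = 10, len = 2000,
                          fs = 125, labels = c("mi", "baseline"),
                          seed = 1L) {
  d <- nrow(cov_a)
  withr::with_seed(seed, {
    ra <- chol(cov_a)
    rb <- chol(cov_b)
    arr <- array(NA_real_, c(2 * n_per_class, d, len))
    for (i in seq_len(n_per_class)) {
      arr[i, , ] <- t(ra) %*% matrix(rnorm(d * len), d, len)
      arr[n_per_class + i, , ] <- t(rb) %*% matrix(rnorm(d * len), d, len)
    }
    trial_set(arr,
              rep(labels, each = n_per_class),
              rep(NA_character_, 2 * n_per_class),
              paste0("g", seq_len(2 * n_per_class)), fs)
  })
}

# random SPD matrix with unit trace
random_spd <- function(d, seed) {
  withr::with_seed(seed, {
    a <- matrix(rnorm(d * d), d)
    s <- crossprod(a) + diag(d) * 0.1
    s / sum(diag(s))
  })
}
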