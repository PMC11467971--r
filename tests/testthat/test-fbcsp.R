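# Filter-bank CSP, mutual-information selection, and the two-layer variant.

make_band_trials <- function(n_per_class = 8, len = 1000, seed = 2) {
  # 8-channel trials with a mu-band class effect on channel 1
  withr::with_seed(seed, {
    arr <- array(rnorm(2 * n_per_class * 8 * len, sd = 0.3),
                 c(2 * n_per_class, 8, len))
    flt <- cspmi:::design_butter(band_spec(9, 13, order = 4), 125)
    for (i in seq_len(2 * n_per_class)) {
      src <- cspmi:::filtfilt_even(flt, rnorm(len))
      src <- src / sd(src)
      gain <- if (i <= n_per_class) 1 else 0.4     # second class attenuated
      arr[i, 1, ] <- arr[i, 1, ] + gain * src
    }
    trial_set(arr, rep(c("baseline", "mi"), each = n_per_class),
              rep(NA_character_, 2 * n_per_class),
              paste0("g", seq_len(2 * n_per_class)), 125)
  })
}

test_that("mutual information scores match the plug-in formula and bounds", {
  lab <- rep(c("a", "b"), each = 40)
  # constant feature -> 0 bits
  expect_identical(unname(mutual_information_scores(
    cbind(rep(1, 80)), lab)), 0)
  # feature = label, balanced -> 1 bit
  x <- as.numeric(lab == "b")
  expect_equal(unname(mutual_information_scores(cbind(x), lab)), 1,
               tolerance = 1e-12)
  # constructed 2x2 joint ((30,10),(10,30)) vs the hand formula
  x2 <- c(rep(0, 30), rep(1, 10), rep(0, 10), rep(1, 30))
  mi <- unname(mutual_information_scores(cbind(x2), lab))
  expect_equal(mi, mi_from_table(matrix(c(30, 10, 10, 30), 2)),
               tolerance = 1e-12)
  expect_error(mutual_information_scores(cbind(x2), rep("a", 80)),
               "constant")
})

test_that("FBCSP concatenates 18 features and selects by MI", {
  ts <- make_band_trials()
  m <- fit_fbcsp(ts, filter_bank(), n_pairs = 3, k_selected = 6)
  expect_length(m$mi_scores, 18)           # 3 bands x 6 filters
  expect_length(m$selected_indices, 6)
  expect_identical(anyDuplicated(m$selected_indices), 0L)
  ft <- extract_features(m, ts)
  expect_identical(dim(feature_matrix(ft)), c(16L, 6L))
  expect_identical(ft$group, ts$groups)    # row order preserved
  # k = all -> identity selection
  m18 <- fit_fbcsp(ts, filter_bank(), k_selected = 18)
  expect_identical(m18$selected_indices, 1:18)
  # the mu-band effect should put a first-band feature among the selected
  expect_true(any(m$selected_indices <= 6))
})

test_that("a label-copy feature is ranked first by the MI criterion", {
  withr::with_seed(7, feats <- matrix(rnorm(80 * 5), 80))
  lab <- rep(c("a", "b"), each = 40)
  feats[, 3] <- as.numeric(lab == "b")
  mi <- mutual_information_scores(feats, lab)
  expect_identical(which.max(mi), 3L)
})

test_that("FBCSSP stacks per-band projections and reduces its feature count", {
  ts <- make_band_trials()
  m <- fit_fbcssp(ts, filter_bank(), n_pairs_l1 = 3, n_pairs_l2 = 3)
  expect_identical(ncol(m$layer2$weights), 18L)   # 3 bands x 6 components
  ft <- extract_features(m, ts)
  expect_identical(ncol(feature_matrix(ft)), 6L)
  expect_error(fit_fbcssp(ts, filter_bank(), n_pairs_l1 = 1, n_pairs_l2 = 4),
               "too small")
})

test_that("single-band full-rank FBCSSP reproduces the single-layer spectrum", {
  ts <- make_band_trials()
  one_band <- filter_bank(list(band_spec(8, 30)))
  # layer 1 keeps all 8 components: an invertible linear transform, so
  # layer-2 generalized eigenvalues must equal the single-layer ones under
  # the same (unnormalized) covariance estimator
  m2 <- fit_fbcssp(ts, one_band, n_pairs_l1 = 4, n_pairs_l2 = 4)
  filt <- bandpass_zero_phase(ts, band_spec(8, 30))
  m1 <- fit_csp_trials(filt, n_pairs = 4, normalization = "none")
  expect_equal(sort(m2$layer2$eigenvalues), sort(m1$eigenvalues),
               tolerance = 1e-6)
})

test_that("identical class covariances propagate lambda = 0.5 to layer 2", {
  # both classes drawn from the same distribution, huge trials
  ts <- toy_trial_set(diag(4), diag(4), n_per_class = 4, len = 8000)
  m <- fit_fbcssp(ts, filter_bank(list(band_spec(8, 30))),
                  n_pairs_l1 = 2, n_pairs_l2 = 2)
  expect_equal(m$layer2$eigenvalues, rep(0.5, 4), tolerance = 0.05)
})

test_that("full models serialize and round-trip", {
  ts <- make_band_trials()
  fb <- fit_fbcsp(ts, filter_bank(), k_selected = 6)
  fs <- fit_fbcssp(ts, filter_bank(), n_pairs_l1 = 2, n_pairs_l2 = 2)

  p1 <- tempfile(fileext = ".json")
  p2 <- tempfile(fileext = ".json")
  write_model(fb, p1); write_model(fs, p2)
  fb2 <- read_model(p1); fs2 <- read_model(p2)
  expect_equal(fb2$per_band_models[[2]]$weights,
               fb$per_band_models[[2]]$weights, tolerance = 1e-12)
  expect_identical(fb2$selected_indices, fb$selected_indices)
  expect_equal(fs2$layer2$weights, fs$layer2$weights, tolerance = 1e-12)
  # features computed from the restored model agree exactly enough
  expect_equal(feature_matrix(extract_features(fb2, ts)),
               feature_matrix(extract_features(fb, ts)), tolerance = 1e-10)
})
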