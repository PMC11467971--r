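# CSP core: covariance estimation, generalized eigenproblem, features.

test_that("class covariance is trace-normalized and averages per trial", {
  # long white trial -> near identity / C
  ts <- toy_trial_set(diag(4), diag(4), n_per_class = 1, len = 20000)
  cv <- class_covariance(ts, "mi")
  expect_equal(sum(diag(cv$matrix)), 1, tolerance = 1e-9)
  expect_equal(cv$matrix, diag(4) / 4, tolerance = 0.02)
  # two trials with known covariances -> mean of the normalized pair
  k1 <- matrix(c(2, 1, 1, 2), 2)
  k2 <- matrix(c(1, 0, 0, 3), 2)
  arr <- array(NA_real_, c(2, 2, 50000))
  withr::with_seed(8, {
    arr[1, , ] <- t(chol(k1)) %*% matrix(rnorm(1e5), 2)
    arr[2, , ] <- t(chol(k2)) %*% matrix(rnorm(1e5), 2)
  })
  ts2 <- trial_set(arr, c("a", "a"), c(NA, NA), c("g1", "g2"), 125)
  cv2 <- class_covariance(ts2, "a")
  expected <- (k1 / sum(diag(k1)) + k2 / sum(diag(k2))) / 2
  expect_equal(cv2$matrix, expected, tolerance = 0.02)
  expect_identical(cv2$n_trials_averaged, 2L)
  expect_error(class_covariance(ts2, "zz"), "no trials")
  # zero-variance trial is reported by name
  arr[2, , ] <- 0
  ts3 <- trial_set(arr, c("a", "a"), c(NA, NA), c("g1", "g2"), 125)
  expect_error(class_covariance(ts3, "a"), "zero variance")
})

test_that("diagonal covariances solve analytically and symmetric ones tie", {
  m <- fit_csp(diag(c(2, 1)) / 3, diag(c(1, 2)) / 3, n_pairs = 1)
  expect_equal(m$eigenvalues, c(2 / 3, 1 / 3), tolerance = 1e-7)
  # filters along the coordinate axes (composite = I so unit axis vectors)
  expect_equal(abs(m$weights), diag(2), tolerance = 1e-7)
  s <- random_spd(4, 5)
  same <- fit_csp(s, s, n_pairs = 2)
  expect_equal(same$eigenvalues, rep(0.5, 4), tolerance = 1e-9)
  expect_error(fit_csp(s, s, n_pairs = 3), "exceeds")
})

test_that("extreme eigenvalues match a brute-force sphere search", {
  for (seed in 1:6) {
    d <- 3 + seed %% 3
    ca <- random_spd(d, seed)
    cb <- random_spd(d, seed + 100)
    m <- fit_csp(ca, cb, n_pairs = 1)
    comp <- ca + cb
    hi <- sphere_max_ratio(ca, comp, seed = seed)
    lo <- sphere_min_ratio(ca, comp, seed = seed)
    expect_equal(m$eigenvalues[1], hi, tolerance = 0.01)
    expect_equal(m$eigenvalues[2], lo, tolerance = 0.01)
  }
})

test_that("W simultaneously diagonalizes both class covariances", {
  ca <- random_spd(6, 21)
  cb <- random_spd(6, 22)
  m <- fit_csp(ca, cb, n_pairs = 3)
  w <- m$weights
  expect_equal(w %*% (ca + cb) %*% t(w), diag(6), tolerance = 1e-8)
  wa <- w %*% ca %*% t(w)
  expect_equal(wa, diag(m$eigenvalues), tolerance = 1e-8)
  wb <- w %*% cb %*% t(w)
  expect_equal(diag(wb), 1 - m$eigenvalues, tolerance = 1e-8)
  expect_equal(sum(diag(wa)) + sum(diag(wb)), 6, tolerance = 1e-8)
  # ordering: first pairs descend from the top, last ascend from the bottom
  expect_true(all(diff(m$eigenvalues[1:3]) <= 0))
  expect_true(all(diff(m$eigenvalues[4:6]) >= 0))
  expect_true(max(m$eigenvalues[4:6]) <= min(m$eigenvalues[1:3]))
})

test_that("channel permutation permutes filter columns, features unchanged", {
  ca <- random_spd(5, 31)
  cb <- random_spd(5, 32)
  p <- diag(5)[c(3, 1, 5, 2, 4), ]
  m1 <- fit_csp(ca, cb, n_pairs = 2)
  m2 <- fit_csp(p %*% ca %*% t(p), p %*% cb %*% t(p), n_pairs = 2)
  expect_equal(abs(m2$weights %*% p), abs(m1$weights), tolerance = 1e-8)
  withr::with_seed(9, y <- matrix(rnorm(5 * 400), 5))
  f1 <- log_variance_features(apply_spatial_filter(m1, y))
  f2 <- log_variance_features(apply_spatial_filter(m2, p %*% y))
  expect_equal(f1, f2, tolerance = 1e-8)
})

test_that("projection is the plain linear map W Y", {
  y <- matrix(c(1, 2, 3, 4, 5, 6), 2, byrow = TRUE)
  id <- structure(list(weights = diag(2), eigenvalues = c(0.5, 0.5),
                       n_pairs = 1L, class_order = c("a", "b")),
                  class = "csp_model")
  expect_identical(apply_spatial_filter(id, y), y)
  perm <- id; perm$weights <- matrix(c(0, 1, 1, 0), 2)
  expect_identical(apply_spatial_filter(perm, y), y[2:1, ])
  had <- id; had$weights <- matrix(c(1, 1, 1, -1), 2, byrow = TRUE) / sqrt(2)
  expect_equal(apply_spatial_filter(had, y),
               rbind(colSums(y), y[1, ] - y[2, ]) / sqrt(2))
  expect_error(apply_spatial_filter(id, matrix(0, 3, 4)), "channels")
})

test_that("log-variance features normalize, scale-invariantly", {
  withr::with_seed(4, y <- matrix(rnorm(6 * 5000), 6))
  y <- y / sqrt(cspmi:::row_vars(y))          # exactly unit variances
  expect_equal(log_variance_features(y), rep(log(1 / 6), 6),
               tolerance = 1e-9)
  y2 <- rbind(sqrt(3) * y[1, ], y[2, ])
  expect_equal(log_variance_features(y2), log(c(0.75, 0.25)),
               tolerance = 1e-9)
  expect_equal(log_variance_features(7.3 * y2), log_variance_features(y2),
               tolerance = 1e-12)
  expect_equal(log_variance_features(y2, normalize = FALSE),
               c(log(3), 0), tolerance = 1e-9)
  expect_error(log_variance_features(rbind(y[1, ], 0)), "zero-variance")
})

test_that("model serialization round-trips losslessly", {
  ca <- random_spd(5, 41)
  cb <- random_spd(5, 42)
  m <- fit_csp(ca, cb, n_pairs = 2)
  path <- tempfile(fileext = ".json")
  write_model(m, path)
  m2 <- read_model(path)
  expect_equal(m2$weights, m$weights, tolerance = 1e-12)
  expect_equal(m2$eigenvalues, m$eigenvalues, tolerance = 1e-12)
  expect_identical(m2$n_pairs, m$n_pairs)
})
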