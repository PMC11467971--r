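# Assumption checks, directional t-tests, and the significance matrix.

test_that("assumption checks behave under the null and on degenerate input", {
  p <- sapply(1:100, function(s) {
    withr::with_seed(s, {
      a <- rnorm(10)
      b <- rnorm(10)
    })
    check_assumptions(a, b)
  })
  # each test's null retention rate is ~95%; demand at least 90/100
  expect_gte(sum(p["shapiro_a", ] > 0.05), 90)
  expect_gte(sum(p["shapiro_b", ] > 0.05), 90)
  expect_gte(sum(p["levene", ] > 0.05), 90)
  expect_error(check_assumptions(rep(1, 10), rnorm(10)), "constant")
  withr::with_seed(2, x <- rnorm(10))
  expect_gt(check_assumptions(x, x)[["levene"]], 0.99)
})

test_that("the directional t-test matches the closed form and base R", {
  a <- c(0.9, 0.8, 0.85)
  b <- c(0.6, 0.65, 0.7)
  cell <- compare_methods(a, b, "ACC", check = FALSE)
  # closed-form pooled-variance statistic computed independently
  sp2 <- (2 * var(a) + 2 * var(b)) / 4
  t_hand <- (mean(a) - mean(b)) / sqrt(sp2 * (2 / 3))
  expect_equal(cell$t_statistic, t_hand, tolerance = 1e-12)
  expect_equal(cell$p_value, pt(t_hand, 4, lower.tail = FALSE),
               tolerance = 1e-12)
  expect_true(cell$significant)
  # agreement with stats::t.test on non-degenerate data
  withr::with_seed(30, {
    x <- rnorm(10, 0.8, 0.05)
    y <- rnorm(10, 0.7, 0.05)
  })
  ref <- t.test(x, y, var.equal = TRUE, alternative = "greater")
  ours <- compare_methods(x, y, "ACC", check = FALSE)
  expect_equal(ours$t_statistic, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(ours$p_value, ref$p.value, tolerance = 1e-12)
})

test_that("equal samples give p = 0.5; overwhelming separation rejects", {
  withr::with_seed(3, a <- rnorm(8, 0.7, 0.03))
  eq <- compare_methods(a, a, "ACC", check = FALSE)
  expect_equal(eq$t_statistic, 0)
  expect_equal(eq$p_value, 0.5)
  expect_false(eq$significant)
  big <- compare_methods(a + 10 * sd(a), a, "ACC", check = FALSE)
  expect_lt(big$p_value, 0.001)
  expect_true(big$significant)
  # FPR direction: lower is better for the first sample
  fpr <- compare_methods(a - 10 * sd(a), a, "FPR", check = FALSE)
  expect_true(fpr$significant)
  expect_error(compare_methods(1, 1:3, "ACC"), "at least two")
})

test_that("swapping samples with the opposite direction preserves p", {
  withr::with_seed(8, {
    a <- rnorm(10, 0.8, 0.05)
    b <- rnorm(10, 0.75, 0.05)
  })
  p_acc <- compare_methods(a, b, "ACC", check = FALSE)$p_value
  p_fpr <- compare_methods(b, a, "FPR", check = FALSE)$p_value
  expect_equal(p_acc, p_fpr, tolerance = 1e-12)
})

test_that("shifting the better sample up never increases the ACC p-value", {
  withr::with_seed(9, {
    a <- rnorm(10, 0.75, 0.05)
    b <- rnorm(10, 0.74, 0.05)
  })
  p0 <- compare_methods(a, b, "ACC", check = FALSE)$p_value
  for (shift in c(0.01, 0.05, 0.2)) {
    expect_lte(compare_methods(a + shift, b, "ACC", check = FALSE)$p_value,
               p0)
  }
})

test_that("the significance table covers all cells and flags planted gaps", {
  # synthetic eval table: 6 subjects, CSP engineered far better than FBCSSP
  grid <- expand.grid(subject = 1:6, session = 1:2,
                      method = c("csp", "fbcsp", "fbcssp"),
                      segmentation = c("tw0", "tw3"),
                      speed = c("low", "high"), fold = 1:5,
                      stringsAsFactors = FALSE)
  withr::with_seed(17, {
    base_acc <- ifelse(grid$method == "fbcssp", 0.55, 0.82)
    grid$acc <- pmin(1, base_acc + rnorm(nrow(grid), 0, 0.03))
    grid$fpr <- pmax(0, ifelse(grid$method == "fbcssp", 0.45, 0.15) +
                       rnorm(nrow(grid), 0, 0.03))
  })
  sig <- build_significance_table(grid)
  expect_identical(nrow(sig), 48L)           # 2 sess x 2 seg x 2 met x 2 sp x 3 pairs
  cvf <- sig[sig$method_a == "csp" & sig$method_b == "fbcssp", ]
  expect_true(all(cvf$significant))
  cvb <- sig[sig$method_a == "csp" & sig$method_b == "fbcsp", ]
  expect_false(any(cvb$significant))
  expect_true(all(sig$significant == (sig$p < 0.05)))
  m <- render_significance_matrix(sig, 1)
  expect_identical(dim(m), c(3L, 8L))        # 3 pairs x 8 condition columns
  expect_false(anyNA(m))
  # identical samples in every cell -> all marks are tildes
  grid0 <- grid
  acc_one <- grid$acc[grid$method == "csp"]
  for (meth in unique(grid0$method)) grid0$acc[grid0$method == meth] <- acc_one
  grid0$fpr <- 0.2
  sig0 <- build_significance_table(grid0)
  expect_false(any(sig0$significant))
  # dropping every method but one leaves nothing to compare
  expect_error(build_significance_table(grid[grid$method == "csp", ]),
               "at least two")
  # a hole in one condition cell is reported
  hole <- !(grid$method == "csp" & grid$session == 1 & grid$speed == "high")
  expect_error(build_significance_table(grid[hole, ]), "missing condition")
})
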