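test_that("error metrics match their definitions and the rmsd identity", {
  expect_equal(error_stats(1:5, 1:5), list(mue = 0, mse = 0, rmsd = 0))
  set.seed(1)
  p <- rnorm(10); r <- rnorm(10)
  es <- error_stats(p, r)
  expect_equal(es$mue, mean(abs(p - r)))
  expect_equal(es$mse, mean((p - r)^2))
  expect_identical(es$rmsd, sqrt(es$mse))
  # a pair constructed with mse 0.35 prints rmsd 0.59 at 2 d.p.
  d <- sqrt(0.35)
  es2 <- error_stats(c(1, 2, 3) + d, c(1, 2, 3))
  expect_equal(es2$mse, 0.35)
  expect_equal(sprintf("%.2f", es2$rmsd), "0.59")
  expect_error(error_stats(1:3, 1:4), "length")
})

test_that("correlations hit exact limits and tau-b matches pair enumeration", {
  x <- c(1, 2, 3, 5, 8)
  cs <- correlation_stats(x, 2 * x + 1, n_boot = 200, seed = 1)
  expect_equal(cs$pearson$value, 1)
  expect_equal(cs$spearman$value, 1)
  expect_equal(cs$kendall_tau$value, 1)
  cs2 <- correlation_stats(x, -x, n_boot = 200, seed = 1)
  expect_equal(unname(vapply(cs2, `[[`, numeric(1), "value")), c(-1, -1, -1))
  # tie-corrected tau-b against brute-force pair counting, 8 points with ties
  xt <- c(1, 2, 2, 3, 4, 4, 5, 6)
  yt <- c(2, 1, 3, 3, 5, 4, 4, 6)
  cs3 <- correlation_stats(xt, yt, n_boot = 200, seed = 1)
  expect_equal(cs3$kendall_tau$value, kendall_tau_b_brute(xt, yt),
               tolerance = 1e-12)
  expect_error(correlation_stats(rep(1, 5), 1:5, 100, 1), "zero-variance")
})

test_that("linear fit equals the normal-equations solution", {
  expect_equal(linear_fit(1:5, 1:5, 100, 1)$slope$value, 1)
  expect_equal(linear_fit(1:5, 1:5, 100, 1)$intercept$value, 0,
               tolerance = 1e-12)
  lf <- linear_fit(c(0, 1, 2), c(1, 3, 5), 100, 1)
  expect_equal(lf$slope$value, 2)
  expect_equal(lf$intercept$value, 1)
  set.seed(3)
  x <- rnorm(20); y <- rnorm(20)
  lf2 <- linear_fit(x, y, 100, 1)
  X <- cbind(1, x)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  expect_equal(lf2$intercept$value, beta[1], tolerance = 1e-10)
  expect_equal(lf2$slope$value, beta[2], tolerance = 1e-10)
  expect_error(linear_fit(rep(2, 4), 1:4, 100, 1), "constant")
})

test_that("distribution shape statistics match moment definitions", {
  v <- c(-1, -1, 1, 1)
  dr <- distribution_stats(v, n_boot = 200, seed = 1)
  expect_equal(dr$skewness, 0)
  expect_equal(dr$excess_kurtosis, -2)      # equal-mass two-point law
  # against an independent implementation on irregular data
  skip_if_not_installed("e1071")
  set.seed(6)
  w <- rexp(60)
  dr2 <- distribution_stats(w, n_boot = 200, seed = 1)
  expect_equal(dr2$skewness, e1071::skewness(w, type = 1), tolerance = 1e-12)
  expect_equal(dr2$excess_kurtosis, e1071::kurtosis(w, type = 1),
               tolerance = 1e-12)
  # CI order and normality flag on clearly skewed data
  expect_lte(dr2$skewness_ci[1], dr2$skewness)
  expect_gte(dr2$skewness_ci[2], dr2$skewness)
  expect_true(dr2$normality_flag[["skewness"]])
})

test_that("significance semantics use the quadrature-combined error", {
  s1 <- significance_test(0.40, 0.3, 0, 0.16)   # sigma_quad = 0.34
  expect_equal(s1$sigma_quad, sqrt(0.3^2 + 0.16^2))
  r1 <- significance_test(0.40, 0.34, 0, 0)
  expect_true(r1$significant)
  r2 <- significance_test(-0.01, 0.33, 0, 0)
  expect_false(r2$significant)
  r3 <- significance_test(1, 0.1, 1, 0.1)
  expect_false(r3$significant)
  # z scales the verdict
  expect_true(significance_test(0.5, 0.2, 0, 0.2, z = 1)$significant)
  expect_false(significance_test(0.5, 0.2, 0, 0.2, z = 2)$significant)
})

test_that("comparison statistics are invariant under pair permutation", {
  set.seed(12)
  p <- rnorm(12); r <- p + rnorm(12, 0, 0.3)
  perm <- sample(12)
  a <- error_stats(p, r); b <- error_stats(p[perm], r[perm])
  expect_equal(a, b)
  ca <- correlation_stats(p, r, 100, 1)
  cb <- correlation_stats(p[perm], r[perm], 100, 1)
  expect_equal(ca$pearson$value, cb$pearson$value)
  expect_equal(ca$kendall_tau$value, cb$kendall_tau$value)
  la <- linear_fit(p, r, 100, 1); lb <- linear_fit(p[perm], r[perm], 100, 1)
  expect_equal(la$slope$value, lb$slope$value)
})

test_that("bootstrap CIs tighten as the sample grows", {
  width <- vapply(c(10, 50, 200), function(n) {
    set.seed(100 + n)
    x <- rnorm(n); y <- x + rnorm(n, 0, 0.5)
    cs <- correlation_stats(x, y, n_boot = 500, seed = 1)
    diff(cs$pearson$ci)
  }, numeric(1))
  expect_true(all(diff(width) < 0))
})

test_that("comparison report assembles all properties with CIs", {
  set.seed(2)
  ref <- rnorm(10); pred <- ref + rnorm(10, 0, 0.4)
  cr <- comparison_report(pred, ref, n_boot = 300, seed = 1)
  expect_identical(cr$rmsd$value, sqrt(cr$mse$value))
  for (p in c("mue", "mse", "rmsd", "pearson", "spearman", "kendall_tau",
              "slope", "intercept")) {
    expect_lte(cr[[p]]$ci[1], cr[[p]]$value + 1e-12)
    expect_gte(cr[[p]]$ci[2], cr[[p]]$value - 1e-12)
  }
  expect_match(alchemr:::format_ci(0.51, c(0.38, 0.64)),
               "0.51[0.38, 0.64]", fixed = TRUE)
})
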