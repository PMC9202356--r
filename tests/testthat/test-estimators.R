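test_that("ti_integrate is exact for constant and linear gradients", {
  sch <- build_lambda_schedule(13)
  expect_equal(ti_integrate(rep(3.5, 13), sch), 3.5)
  g <- 2 * sch$lambdas + 1            # trapezoid is exact for linear
  expect_equal(ti_integrate(g, sch), 2)
  # non-uniform grid
  sch2 <- build_lambda_schedule(5, lambdas = c(0, 0.1, 0.3, 0.7, 1))
  expect_equal(ti_integrate(2 * sch2$lambdas + 1, sch2), 2)
  expect_error(ti_integrate(c(1, NA, rep(1, 11)), sch), "window")
})

test_that("TI on analytic Gaussian-chain gradients recovers the closed form", {
  # log-linear force constants give a constant expected gradient, so the
  # trapezoid rule is exact; use exact per-window expectations
  sys <- gaussian_chain_system(13, kf = c(1, 4), mu = c(0, 1))
  # E[du/dl] at window k: 0.5 kf'(l)/kf(l) (quadratic term) + 0 (mu term)
  means <- 0.5 * sys$dkf_fun(sys$lambdas) / sys$kf_fun(sys$lambdas)
  sch <- build_lambda_schedule(13)
  expect_equal(ti_integrate(means, sch), gaussian_chain_analytic(sys)[13],
               tolerance = 1e-12)
})

test_that("TIES ensemble estimate covers the analytic value and degenerates correctly", {
  ss <- chain_samples(K = 13, n = 500, R = 5, seed = 2)
  truth <- gaussian_chain_analytic(default_chain())[13]
  ti <- ties_estimate(ss, n_boot = 2000, seed = 1)
  expect_lt(abs(ti$delta_g - truth), 3 * ti$sem)
  expect_length(ti$replica_values, 5)
  # identical replicas: SEM exactly 0
  ss0 <- ss
  for (k in seq_along(ss0$windows)) {
    for (r in 2:5) ss0$windows[[k]][[r]] <- ss0$windows[[k]][[1]]
  }
  ti0 <- ties_estimate(ss0, n_boot = 500, seed = 1)
  expect_equal(ti0$sem, 0)
  expect_equal(ti0$delta_g,
               ti_integrate(vapply(ss0$windows,
                                   function(w) mean(w[[1]]$dudl),
                                   numeric(1)), ss0$schedule))
  # single replica: point estimate with SEM flagged unavailable
  ss1 <- chain_samples(K = 5, n = 100, R = 1, seed = 3)
  ti1 <- ties_estimate(ss1, n_boot = 500, seed = 1)
  expect_true(is.na(ti1$sem))
  expect_true(is.finite(ti1$delta_g))
})

test_that("MBAR solves trivial gauges and symmetric two-state inputs", {
  u1 <- matrix(rnorm(50), 50, 1)
  fit1 <- mbar_solve(u1, 50)
  expect_equal(fit1$f, 0)
  # identical states: zero free-energy difference, uniform weights
  v <- rnorm(40)^2
  u2 <- cbind(v, v)
  fit2 <- mbar_solve(u2, c(20, 20))
  expect_equal(fit2$f[2], 0, tolerance = 1e-12)
  expect_equal(unique(round(rowSums(fit2$W * 20), 10)), 1)
  expect_equal(as.vector(fit2$W), rep(1 / 40, 80), tolerance = 1e-12)
})

test_that("MBAR recovers the Gaussian chain within its analytic error", {
  ss <- chain_samples(K = 13, n = 1000, R = 1, seed = 8)
  p <- pooled_u(ss)
  fit <- mbar_solve(p$u, p$N_k)
  truth <- gaussian_chain_analytic(default_chain())
  sem <- mbar_analytic_sem(fit$W, p$N_k, 1, 13)
  expect_lt(abs(fit$f[13] - truth[13]), 3 * sem)
  # weight identities at convergence
  expect_lt(max(abs(colSums(fit$W) - 1)), 1e-10)
  expect_lt(max(abs(rowSums(sweep(fit$W, 2, p$N_k, "*")) - 1)), 1e-10)
})

test_that("MBAR restricted to two states equals the independent BAR solver", {
  ss <- chain_samples(K = 13, n = 400, R = 1, seed = 12)
  for (k in c(1, 5, 11)) {
    u <- rbind(ss$windows[[k]][[1]]$u_cross[, c(k, k + 1)],
               ss$windows[[k + 1]][[1]]$u_cross[, c(k, k + 1)])
    N_k <- c(400, 400)
    bar <- bar_estimate(u, N_k)
    mb <- mbar_solve(u, N_k)
    expect_lt(abs(bar$delta_f - mb$f[2]), 1e-8)
  }
  # strong-overlap endpoints recover the closed form
  set.seed(99)
  x0 <- rnorm(5000, 0, 1); x1 <- rnorm(5000, 0, 0.5)
  u <- cbind(0.5 * c(x0, x1)^2, 0.5 * 4 * c(x0, x1)^2)
  bar <- bar_estimate(u, c(5000, 5000))
  expect_equal(bar$delta_f, 0.5 * log(4), tolerance = 0.05)
  expect_error(bar_estimate(u[, 1, drop = FALSE], 10000), "two states")
})

test_that("Zwanzig estimates shifts exactly and brackets the truth", {
  u_i <- rnorm(100)^2
  expect_equal(zwanzig_estimate(u_i, u_i)$delta_f, 0)
  expect_equal(zwanzig_estimate(u_i, u_i + 1.3)$delta_f, 1.3)
  expect_equal(zwanzig_estimate(u_i, u_i)$ess, 100)
  # forward and negated-reverse estimates agree with the closed form within
  # bootstrap uncertainty on adjacent Gaussian states
  set.seed(4)
  kf <- c(1, 2); n <- 10000
  x0 <- rnorm(n, 0, 1 / sqrt(kf[1])); x1 <- rnorm(n, 0, 1 / sqrt(kf[2]))
  truth <- 0.5 * log(kf[2] / kf[1])
  du_f <- 0.5 * kf[2] * x0^2 - 0.5 * kf[1] * x0^2
  fwd <- zwanzig_estimate(0.5 * kf[1] * x0^2, 0.5 * kf[2] * x0^2)$delta_f
  rev <- -zwanzig_estimate(0.5 * kf[2] * x1^2, 0.5 * kf[1] * x1^2)$delta_f
  boot_sem <- sd(replicate(200, {
    i <- sample.int(n, n, replace = TRUE)
    -log(mean(exp(-du_f[i])))
  }))
  expect_lt(abs(fwd - truth), 3 * boot_sem)
  expect_lt(abs(rev - truth), max(3 * boot_sem * 10, 0.1))
  # the poorly-sampled direction has far lower effective sample size
  ess_f <- zwanzig_estimate(0.5 * kf[1] * x0^2, 0.5 * kf[2] * x0^2)$ess
  ess_r <- zwanzig_estimate(0.5 * kf[2] * x1^2, 0.5 * kf[1] * x1^2)$ess
  expect_gt(ess_f, ess_r)
})

test_that("the thermodynamic cycle composes legs with quadrature errors", {
  a <- alchemr:::new_free_energy_result(2, 3, rep(2, 3), "TI")
  b <- alchemr:::new_free_energy_result(0.5, 4, rep(0.5, 3), "TI")
  cy <- thermo_cycle(a, b)
  expect_equal(cy$ddg, 1.5)
  expect_equal(cy$sem, 5)             # 3-4-5 quadrature
  swapped <- thermo_cycle(b, a)
  expect_equal(swapped$ddg, -1.5)
  expect_equal(swapped$sem, cy$sem)
  expect_equal(thermo_cycle(a, a)$ddg, 0)
  c2 <- alchemr:::new_free_energy_result(1, 1, 1, "MBAR")
  expect_error(thermo_cycle(a, c2), "estimator")
})

test_that("estimator family concords on high-overlap data", {
  # TI, ensemble MBAR, stepwise BAR and forward Zwanzig agree within
  # combined uncertainties on a gentle chain
  ss <- chain_samples(K = 13, n = 500, R = 5, seed = 77)
  truth <- gaussian_chain_analytic(default_chain())[13]
  ti <- ties_estimate(ss, n_boot = 1000, seed = 1)
  mb <- mbar_ensemble_estimate(ss, n_boot = 1000, seed = 2)
  expect_lt(abs(ti$delta_g - mb$delta_g), 3 * sqrt(ti$sem^2 + mb$sem^2))
  # stepwise BAR across all windows, replica 1
  bar_total <- sum(vapply(1:12, function(k) {
    u <- rbind(ss$windows[[k]][[1]]$u_cross[, c(k, k + 1)],
               ss$windows[[k + 1]][[1]]$u_cross[, c(k, k + 1)])
    bar_estimate(u, c(500, 500))$delta_f
  }, numeric(1)))
  expect_lt(abs(bar_total - truth), 0.1)
  zw_total <- sum(vapply(1:12, function(k) {
    zwanzig_estimate(ss$windows[[k]][[1]]$u_cross[, k],
                     ss$windows[[k]][[1]]$u_cross[, k + 1])$delta_f
  }, numeric(1)))
  expect_lt(abs(zw_total - truth), 0.15)
})
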