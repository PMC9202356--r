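test_that("Gaussian chain sampling is deterministic and moment-correct", {
  ss1 <- chain_samples(K = 5, n = 1000, R = 3, seed = 11)
  ss2 <- chain_samples(K = 5, n = 1000, R = 3, seed = 11)
  expect_identical(ss1$windows, ss2$windows)       # bit-identical regeneration
  expect_identical(ss1$manifest$derived_seeds, ss2$manifest$derived_seeds)
  # distinct replicas come from distinct streams
  expect_false(identical(ss1$windows[[1]][[1]]$x, ss1$windows[[1]][[2]]$x))
  sys <- default_chain(5)
  for (k in c(1, 3, 5)) {
    x <- unlist(lapply(ss1$windows[[k]], `[[`, "x"))
    kf <- sys$force_constants[k]
    expect_lt(abs(mean(x) - sys$centers[k]), 4 / sqrt(length(x) * kf))
    expect_equal(stats::var(x), 1 / kf, tolerance = 0.1)
  }
  # u_cross column k at window k is the sampled state's own reduced potential
  k <- 3
  x <- ss1$windows[[k]][[1]]$x
  expect_equal(ss1$windows[[k]][[1]]$u_cross[, k],
               0.5 * sys$force_constants[k] * (x - sys$centers[k])^2)
})

test_that("gradient column is consistent with cross-evaluations across windows", {
  # du/dlambda at window k should match the finite difference of the
  # cross-evaluated reduced potentials at the neighboring windows
  ss <- chain_samples(K = 13, n = 200, R = 2, seed = 4)
  dl <- diff(ss$schedule$lambdas)[1]
  for (k in c(2, 7, 12)) {
    rep <- ss$windows[[k]][[1]]
    fd <- (rep$u_cross[, k + 1] - rep$u_cross[, k - 1]) / (2 * dl)
    expect_equal(rep$dudl, fd, tolerance = 0.05)
  }
})

test_that("add_autocorrelation builds a stationary AR(1) with preserved moments", {
  set.seed(9)
  z <- rnorm(1e4)
  expect_identical(add_autocorrelation(z, 0), z)
  for (rho in c(0.5, 0.9)) {
    y <- add_autocorrelation(z, rho)
    expect_equal(mean(y), mean(z), tolerance = 1e-12)
    expect_equal(sd(y), sd(z), tolerance = 1e-12)
    r1 <- stats::acf(y, lag.max = 1, plot = FALSE)$acf[2]
    expect_lt(abs(r1 - rho), 0.05)
  }
  # statistical inefficiency of AR(1) approaches (1+rho)/(1-rho)
  y <- add_autocorrelation(rnorm(1e4), 0.6)
  g <- statistical_inefficiency(y)$g
  expect_equal(g, (1 + 0.6) / (1 - 0.6), tolerance = 0.2)
  expect_error(add_autocorrelation(z, 1), "rho")
})

test_that("slow-switch mixture: rapid mixing agrees with the analytic mixture", {
  sys <- gaussian_chain_system(5, kf = c(1, 1), mu = c(0, 0))
  sp <- generator_spec(sys, n_samples = 800, n_replicas = 4, seed = 21)
  # symmetric modes (zero gap): ensemble-mean position is 0 within CI
  sw0 <- sample_slow_switch_mixture(sp, mode_gap = 0, mode_switch_prob = 1)
  xs <- unlist(lapply(sw0$windows[[3]], `[[`, "x"))
  expect_lt(abs(mean(xs)), 4 * sd(xs) / sqrt(length(xs)))
  expect_equal(sw0$manifest$analytic_f, rep(0, 5))
  # fast switching: per-replica dG agree with the analytic mixture value
  sw1 <- sample_slow_switch_mixture(sp, mode_gap = 2, mode_switch_prob = 1)
  truth <- sw1$manifest$analytic_f[5]
  expect_equal(truth, -log((1 + exp(-2)) / 2))
  mb <- mbar_ensemble_estimate(sw1, n_boot = 1000, seed = 3)
  expect_lt(abs(mb$delta_g - truth), 4 * max(mb$sem, 1e-3))
})

test_that("slow-switch mixture reproduces the trapped-replica spread", {
  sys <- gaussian_chain_system(13, kf = c(1, 1), mu = c(0, 0))
  sp <- generator_spec(sys, n_samples = 1000, n_replicas = 5, seed = 31)
  sw <- sample_slow_switch_mixture(sp, mode_gap = 2, mode_switch_prob = 1e-4)
  ec <- error_comparison(sw, n_boot = 1000, seed = 1)
  # across-replica spread far exceeds the single-trajectory analytic estimate
  expect_gt(sd(ec$per_replica_dg),
            2 * mean(ec$analytic_sem_per_replica))
})

test_that("toy LJ Metropolis sampling hits the ideal-gas limit at zero coupling", {
  sys <- toy_lj_system(softcore = softcore_params(alpha = 0.5, c = 2))
  sch <- build_lambda_schedule(5, "one_step")
  sp <- generator_spec(sys, n_samples = 2000, n_replicas = 1, seed = 5)
  ss <- metropolis_toy_lj(sp, sch, store_u_cross = TRUE)
  # final window of the disappearing leg: coupling 0, uniform positions
  last <- ss$windows[[5]][[1]]
  expect_equal(last$acceptance_rate, 1)          # every move accepted
  expect_equal(unique(as.vector(last$u_cross[, 5])), 0)
  ks <- suppressWarnings(
    stats::ks.test(last$x[, 1] / sys$box_length, "punif"))
  expect_gt(ks$p.value, 0.01)
  # coupled windows carry finite energies and a sane tuned acceptance rate
  expect_true(all(is.finite(ss$windows[[1]][[1]]$u_cross)))
  # one particle in a mostly empty box: most moves land in flat regions, so
  # the acceptance rate sits well above the tuning floor
  expect_gt(ss$windows[[1]][[1]]$acceptance_rate, 0.15)
})

test_that("toy LJ insertion free energy matches the quadrature oracle", {
  # one fixed neighbor: dG of decoupling from the 3-D integral of
  # -log <exp(-beta U)> over the box
  sys <- toy_lj_system(epsilon = 0.3, softcore = softcore_params(alpha = 0.5, c = 2))
  sch <- build_lambda_schedule(9, "one_step")
  sp <- generator_spec(sys, n_samples = 1500, n_replicas = 3, seed = 17)
  ss <- metropolis_toy_lj(sp, sch)
  mb <- mbar_ensemble_estimate(ss, n_boot = 1000, seed = 2)
  # deterministic oracle: midpoint quadrature on a 3-D grid
  L <- sys$box_length
  g <- seq(L / 80, L - L / 80, length.out = 40)
  gr <- as.matrix(expand.grid(g, g, g))
  d <- sweep(gr, 2, rep(L / 2, 3)); d <- d - L * round(d / L)
  r <- sqrt(rowSums(d^2))
  u <- sys$beta * softcore_lj_energy(r, 1, sys$epsilon, sys$sigma, sys$softcore)
  df_true <- (0 - (-log(mean(exp(-u))))) / sys$beta   # coupled -> uncoupled
  expect_lt(abs(mb$delta_g - df_true), 3 * mb$sem + 0.02 / sys$beta)
})
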