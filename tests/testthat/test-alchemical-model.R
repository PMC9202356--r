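test_that("soft-core LJ energy recovers the 12-6 limits and the softened core", {
  sc6 <- softcore_params(alpha = 0.5, a = 1, b = 1, c = 6)
  # fully decoupled: zero at any distance
  expect_equal(softcore_lj_energy(c(0.5, 1, 3), 0, sc = sc6), c(0, 0, 0))
  # fully coupled: standard LJ (zero crossing at r = sigma, minimum -epsilon)
  expect_equal(softcore_lj_energy(1, 1, epsilon = 2, sigma = 1, sc = sc6), 0)
  rmin <- 2^(1 / 6)
  expect_equal(softcore_lj_energy(rmin, 1, epsilon = 2, sc = sc6), -2)
  # softened core value from the closed form: denominator term 1.25
  expect_equal(softcore_lj_energy(1, 0.5, epsilon = 1, sc = sc6),
               4 * 0.5 * (1.25^-2 - 1.25^-1))
  expect_equal(softcore_lj_energy(1, 0.5, epsilon = 1, sc = sc6), -0.32)
  # finite at r -> 0 for lam < 1, alpha > 0
  expect_true(is.finite(softcore_lj_energy(1e-12, 0.9, sc = sc6)))
  expect_error(softcore_lj_energy(-1, 0.5), "positive")
  expect_error(softcore_lj_energy(1, 0.5, epsilon = -1), "positive")
})

test_that("soft-core lambda-derivative matches a central finite difference", {
  for (cc in c(2, 6)) {
    sc <- softcore_params(alpha = 0.7, a = 1, b = 1, c = cc)
    h <- 1e-6
    for (lam in c(0.1, 0.5, 0.9)) {
      for (r in c(0.3, 0.9, 1.5)) {
        fd <- (softcore_lj_energy(r, lam + h, sc = sc) -
                 softcore_lj_energy(r, lam - h, sc = sc)) / (2 * h)
        an <- softcore_lj_dlambda(r, lam, sc = sc)
        expect_equal(an, fd, tolerance = 1e-6)
      }
    }
  }
  # at lam = 0 with a = 1 only the prefactor term survives
  sc <- softcore_params(alpha = 0.5, a = 1, b = 1, c = 6)
  r <- 0.8
  A <- 0.5 + r^6
  expect_equal(softcore_lj_dlambda(r, 0, sc = sc),
               4 * (A^-2 - A^-1))
})

test_that("reduced potential applies beta and the optional pV term", {
  st <- alchemical_state(0, 0, temperature = 300)
  expect_equal(reduced_potential(0, st), 0)
  expect_equal(reduced_potential(1, st), 1 / (0.0019872041 * 300),
               tolerance = 1e-10)
  expect_equal(round(reduced_potential(1, st), 4), 1.6774)
  stp <- alchemical_state(0, 0, temperature = 300, pressure = 0)
  expect_equal(reduced_potential(2, stp, volume = 30), reduced_potential(2, st))
  stp1 <- alchemical_state(0, 0, temperature = 300, pressure = 1)
  expect_error(reduced_potential(2, stp1), "volume")
  expect_gt(reduced_potential(2, stp1, volume = 30), reduced_potential(2, st))
})

test_that("lambda schedules hit pure end states and honour the scheme semantics", {
  for (scheme in c("one_step", "two_step")) {
    sch <- build_lambda_schedule(13, scheme)
    expect_equal(sch$lambdas, seq(0, 1, length.out = 13))
    # end states are exact, not approximate
    expect_identical(unname(sch$factors[1, ]), c(1, 1, 0, 0))
    expect_identical(unname(sch$factors[13, ]), c(0, 0, 1, 1))
    # all classes monotone along the path
    expect_true(all(diff(sch$factors[, "elec_dis"]) <= 0))
    expect_true(all(diff(sch$factors[, "vdw_dis"]) <= 0))
    expect_true(all(diff(sch$factors[, "elec_app"]) >= 0))
    expect_true(all(diff(sch$factors[, "vdw_app"]) >= 0))
  }
  # two-step: both electrostatic classes exactly off at the midpoint
  sch2 <- build_lambda_schedule(13, "two_step")
  expect_equal(unname(sch2$factors[7, "elec_dis"]), 0)
  expect_equal(unname(sch2$factors[7, "elec_app"]), 0)
  expect_equal(unname(sch2$factors[7, "vdw_app"]), 1)
  expect_error(build_lambda_schedule(1), "at least 2")
})

test_that("Gaussian chain analytic free energies match numerical quadrature", {
  sys <- gaussian_chain_system(7, kf = c(0.5, 8), mu = c(-1, 2),
                               offset = c(0, 1.5))
  f <- gaussian_chain_analytic(sys)
  expect_equal(f[1], 0)
  # quadrature oracle: f_k = -log integral exp(-u_k) dx on a dense grid
  x <- seq(-60, 60, length.out = 1e6)
  dx <- x[2] - x[1]
  fq <- vapply(seq_len(7), function(k) {
    u <- 0.5 * sys$force_constants[k] * (x - sys$centers[k])^2 + sys$offsets[k]
    -log(sum(exp(-u)) * dx)
  }, numeric(1))
  expect_equal(f, fq - fq[1], tolerance = 1e-8)
  # two-state closed form and translation invariance
  s2 <- gaussian_chain_system(2, kf = c(1, 4), mu = c(0, 0))
  expect_equal(gaussian_chain_analytic(s2)[2], 0.5 * log(4))
  s3 <- gaussian_chain_system(2, kf = c(1, 4), mu = c(5, -3))
  expect_equal(gaussian_chain_analytic(s3), gaussian_chain_analytic(s2))
  s4 <- gaussian_chain_system(3, kf = c(2, 2), mu = c(0, 1))
  expect_equal(gaussian_chain_analytic(s4), c(0, 0, 0))
})

test_that("soft-core energy is continuous in lambda and bounded near r = 0", {
  sc <- softcore_params(alpha = 0.5, c = 6)
  lam <- seq(0, 1, length.out = 201)
  u <- softcore_lj_energy(rep(1.1, 201), lam, sc = sc)
  expect_true(all(is.finite(u)))
  expect_lt(max(abs(diff(u))), 0.1)    # no jumps on a fine lambda grid
  u0 <- softcore_lj_energy(rep(1e-9, 100), seq(0, 0.99, length.out = 100),
                           sc = sc)
  expect_true(all(is.finite(u0)))
})
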