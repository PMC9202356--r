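# Free-energy estimators: ensemble thermodynamic integration (TIES), the
# perturbative family (MBAR / BAR / Zwanzig), and thermodynamic-cycle
# composition of solvent and complex legs.

# row-wise log-sum-exp, overflow safe for |values| up to ~700
logsumexp_rows <- function(m) {
  mx <- m[cbind(seq_len(nrow(m)), max.col(m, ties.method = "first"))]
  mx + log(rowSums(exp(m - mx)))
}

logsumexp <- function(v) {
  mx <- max(v)
  mx + log(sum(exp(v - mx)))
}

#' Trapezoidal thermodynamic integration
#'
#' Integrates per-window gradient expectations over the schedule's global
#' lambda grid with the trapezoid rule. Gradients are reduced (du/dlambda),
#' so the result is a dimensionless free-energy difference; divide by beta to
#' obtain kcal/mol.
#'
#' @param window_means one finite gradient mean per window
#' @param schedule a [build_lambda_schedule()] schedule (its `lambdas` grid is
#'   the quadrature grid)
#' @return the integral (reduced free-energy difference)
#' @export
ti_integrate <- function(window_means, schedule) {
  lam <- schedule$lambdas
  if (length(window_means) != length(lam)) {
    stop("need one gradient mean per window", call. = FALSE)
  }
  bad <- which(!is.finite(window_means))
  if (length(bad)) {
    stop("non-finite gradient mean in window(s) ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  sum(diff(lam) * (window_means[-1] + window_means[-length(lam)]) / 2)
}

# per-replica per-window time means of the gradient: K x R matrix
replica_window_means <- function(samples) {
  K <- samples$n_states; R <- samples$n_replicas
  m <- matrix(0, K, R)
  for (k in seq_len(K)) {
    for (r in seq_len(R)) m[k, r] <- mean(samples$windows[[k]][[r]]$dudl)
  }
  m
}

new_free_energy_result <- function(delta_g, sem, replica_values, estimator,
                                   per_state_f = NULL, extra = list()) {
  stopifnot(is.finite(delta_g), is.na(sem) || sem >= 0)
  structure(c(list(delta_g = delta_g, sem = sem,
                   replica_values = replica_values, estimator = estimator,
                   per_state_f = per_state_f), extra),
            class = "free_energy_result")
}

#' @export
print.free_energy_result <- function(x, ...) {
  cat(sprintf("%s: dG = %.4f +/- %.4f (%d replicas)\n", x$estimator,
              x$delta_g, x$sem, length(x$replica_values)))
  invisible(x)
}

#' Ensemble thermodynamic integration (TIES)
#'
#' The ensemble TI protocol: within each window the per-replica time-averaged
#' gradients are bootstrapped across replicas, giving a window mean and a
#' window standard error sigma(lambda); the window means are integrated with
#' [ti_integrate()] and the window errors propagated through the trapezoid
#' weights by [propagate_ti_error()]. The result is converted to kcal/mol
#' through the sample set's beta.
#'
#' @param samples a `sample_set`
#' @param n_boot bootstrap resamples per window
#' @param seed RNG seed for the bootstrap
#' @return a `free_energy_result` with per-replica TI values attached; with a
#'   single replica the SEM is `NA` (flagged unavailable)
#' @export
ties_estimate <- function(samples, n_boot = 5000, seed = 1) {
  m <- replica_window_means(samples)          # K x R
  K <- nrow(m); R <- ncol(m)
  boot_mean <- numeric(K); boot_sd <- numeric(K)
  set.seed(seed)
  if (R >= 2) {
    for (k in seq_len(K)) {
      idx <- matrix(sample.int(R, n_boot * R, replace = TRUE), n_boot, R)
      bm <- rowMeans(matrix(m[k, idx], n_boot, R))
      boot_mean[k] <- mean(bm)
      boot_sd[k] <- stats::sd(bm)
    }
  } else {
    boot_mean <- m[, 1]
    boot_sd <- rep(NA_real_, K)
  }
  df <- ti_integrate(boot_mean, samples$schedule)
  sem <- if (R >= 2) {
    propagate_ti_error(boot_sd, samples$schedule) / samples$beta
  } else NA_real_
  replica_values <- apply(m, 2, ti_integrate,
                          schedule = samples$schedule) / samples$beta
  new_free_energy_result(df / samples$beta, sem, replica_values, "TI",
                         extra = list(window_means = boot_mean,
                                      window_sigmas = boot_sd))
}

#' Self-consistent MBAR solver
#'
#' Solves the multistate Bennett acceptance ratio equations
#' f_i = -log sum_n exp(-u_i(x_n)) / sum_k N_k exp(f_k - u_k(x_n))
#' for the dimensionless per-state free energies, gauge-fixed to f_1 = 0.
#' Iteration is plain self-consistency with log-sum-exp throughout, switching
#' to damped Newton steps on the maximum-likelihood gradient once the
#' residual falls below 1e-2.
#'
#' @param u_cross N x K matrix: reduced potential of every stored
#'   configuration evaluated in all K states (rows stacked over all windows)
#' @param N_k samples contributed by each state (sum N_k = N, length K)
#' @param tol convergence threshold on max |delta f|
#' @param max_iter iteration cap
#' @return list with `f` (relative dimensionless free energies), `W` (the
#'   N x K normalised weight matrix), `n_iter`, `converged`
#' @export
mbar_solve <- function(u_cross, N_k, tol = 1e-10, max_iter = 10000) {
  u <- as.matrix(u_cross)
  K <- ncol(u); N <- nrow(u)
  if (length(N_k) != K) stop("N_k must have one entry per state", call. = FALSE)
  if (sum(N_k) != N) stop("sum(N_k) must equal nrow(u_cross)", call. = FALSE)
  if (any(!is.finite(u))) stop("u_cross contains non-finite values", call. = FALSE)
  if (K == 1) {
    return(list(f = 0, W = matrix(1 / N, N, 1), n_iter = 0L, converged = TRUE))
  }
  logN <- log(N_k)
  f <- numeric(K)
  res <- Inf
  newton_ready <- FALSE
  for (it in seq_len(max_iter)) {
    shifted <- sweep(-u, 2, logN + f, "+")
    logD <- logsumexp_rows(shifted)
    if (!newton_ready) {
      fnew <- -vapply(seq_len(K), function(i) logsumexp(-u[, i] - logD),
                      numeric(1))
      fnew <- fnew - fnew[1]
    } else {
      W <- exp(sweep(-u - logD, 2, f, "+"))      # N x K
      S <- colSums(W)
      grad <- N_k * (S - 1)
      WN <- sweep(W, 2, N_k, "*")
      H <- diag(N_k * S, K) - crossprod(WN)
      Hr <- H[-1, -1, drop = FALSE]
      gr <- grad[-1]
      delta <- tryCatch(solve(Hr, gr), error = function(e) NULL)
      if (is.null(delta)) {
        fnew <- -vapply(seq_len(K), function(i) logsumexp(-u[, i] - logD),
                        numeric(1))
        fnew <- fnew - fnew[1]
      } else {
        fnew <- f
        fnew[-1] <- f[-1] - delta
      }
    }
    res_new <- max(abs(fnew - f))
    if (newton_ready && res_new > res) newton_ready <- FALSE  # safeguard
    res <- res_new
    f <- fnew
    if (res < tol) break
    if (res < 1e-2) newton_ready <- TRUE
  }
  if (res >= tol) {
    stop(sprintf("MBAR did not converge in %d iterations (residual %.3g)",
                 max_iter, res), call. = FALSE)
  }
  shifted <- sweep(-u, 2, logN + f, "+")
  logD <- logsumexp_rows(shifted)
  W <- exp(sweep(-u - logD, 2, f, "+"))
  list(f = f - f[1], W = W, n_iter = it, converged = TRUE)
}

# stack a replica's cross-evaluations over all windows
stack_replica_u <- function(samples, r) {
  do.call(rbind, lapply(samples$windows, function(w) w[[r]]$u_cross))
}

replica_N_k <- function(samples, r) {
  vapply(samples$windows, function(w) nrow(w[[r]]$u_cross), numeric(1))
}

#' Ensemble MBAR (FEP) estimate
#'
#' The ensemble counterpart of [ties_estimate()] for the perturbative route:
#' MBAR is solved separately on each replica's pooled cross-evaluations, the
#' end-to-end dimensionless free energy of each replica is converted to
#' kcal/mol, and the replica values are bootstrapped for the mean and SEM.
#' A pooled mode (all replicas concatenated into one MBAR solve, SEM from the
#' analytic covariance) is available for single-trajectory comparisons.
#'
#' @param samples a `sample_set` with cross-evaluations
#' @param n_boot bootstrap resamples
#' @param seed RNG seed
#' @param pooled logical; pool replicas into a single MBAR solve
#' @param tol,max_iter passed to [mbar_solve()]
#' @return a `free_energy_result` (estimator `"MBAR"`)
#' @export
mbar_ensemble_estimate <- function(samples, n_boot = 5000, seed = 1,
                                   pooled = FALSE, tol = 1e-10,
                                   max_iter = 10000) {
  R <- samples$n_replicas
  if (pooled) {
    u <- do.call(rbind, lapply(seq_len(R), stack_replica_u, samples = samples))
    N_k <- Reduce(`+`, lapply(seq_len(R), replica_N_k, samples = samples))
    fit <- mbar_solve(u, N_k, tol, max_iter)
    K <- length(fit$f)
    sem <- mbar_analytic_sem(fit$W, N_k, 1, K) / samples$beta
    dg <- fit$f[K] / samples$beta
    return(new_free_energy_result(dg, sem, dg, "MBAR",
                                  per_state_f = fit$f,
                                  extra = list(pooled = TRUE)))
  }
  per_rep <- vapply(seq_len(R), function(r) {
    fit <- mbar_solve(stack_replica_u(samples, r), replica_N_k(samples, r),
                      tol, max_iter)
    fit$f[length(fit$f)]
  }, numeric(1)) / samples$beta
  if (R >= 2) {
    bs <- ensemble_bootstrap(per_rep, n_boot = n_boot, seed = seed)
    new_free_energy_result(bs$mean, bs$sem, per_rep, "MBAR")
  } else {
    new_free_energy_result(per_rep, NA_real_, per_rep, "MBAR")
  }
}

#' Bennett acceptance ratio for two adjacent states
#'
#' Independent two-state solver: the BAR self-consistency condition is reduced
#' to the scalar equation sum_n 1 / (N_0 + N_1 exp(df - u_1 + u_0)) = 1 and
#' solved by bracketed root finding. MBAR restricted to two states solves the
#' same equations, so both routes must agree to solver tolerance.
#'
#' @param u_cross N x 2 matrix of reduced potentials (samples from both
#'   states stacked) evaluated in the two states
#' @param N_k length-2 sample counts; both must be positive
#' @return list with `delta_f` and the achieved root residual
#' @export
bar_estimate <- function(u_cross, N_k) {
  u <- as.matrix(u_cross)
  if (ncol(u) != 2 || length(N_k) != 2) {
    stop("bar_estimate expects exactly two states", call. = FALSE)
  }
  if (any(N_k == 0)) stop("both states need samples", call. = FALSE)
  if (sum(N_k) != nrow(u)) stop("sum(N_k) must equal nrow(u_cross)", call. = FALSE)
  d <- u[, 2] - u[, 1]            # u_1 - u_0 per sample
  gfun <- function(df) {
    # log-stabilised: 1/(N0 + N1 exp(df - d)) summed over samples, minus 1
    e <- df - d
    sum(1 / (N_k[1] + N_k[2] * exp(pmin(e, 700)))) - 1
  }
  # bracket around the Zwanzig forward estimate
  f0 <- zwanzig_estimate(u[seq_len(N_k[1]), 1], u[seq_len(N_k[1]), 2])$delta_f
  lo <- f0 - 50; hi <- f0 + 50
  while (gfun(lo) < 0) lo <- lo - 50
  while (gfun(hi) > 0) hi <- hi + 50
  root <- stats::uniroot(gfun, c(lo, hi), tol = 1e-13)
  list(delta_f = root$root, residual = root$f.root)
}

#' Zwanzig (exponential averaging) estimate
#'
#' One-sided free-energy perturbation from samples of state i to target state
#' j: delta_f = -log < exp(-(u_j - u_i)) >_i. Prone to bias when the target
#' is poorly sampled; the effective sample size of the exponential weights is
#' returned as a diagnostic.
#'
#' @param u_i reduced potentials of the samples evaluated in their own state
#' @param u_j the same samples evaluated in the target state
#' @return list with `delta_f` and `ess` (Kish effective sample size of the
#'   weights)
#' @export
zwanzig_estimate <- function(u_i, u_j) {
  if (length(u_i) != length(u_j)) stop("length mismatch", call. = FALSE)
  w <- -(u_j - u_i)
  n <- length(w)
  lse <- logsumexp(w)
  delta_f <- -(lse - log(n))
  lw <- w - lse
  ess <- 1 / sum(exp(2 * lw))
  list(delta_f = delta_f, ess = ess)
}

#' Compose the thermodynamic cycle
#'
#' ddG = dG_complex - dG_solvent, the relative binding free energy; the leg
#' SEMs combine in quadrature. Sign convention: negative ddG favors binding
#' of the transformed (B) ligand.
#'
#' @param complex_leg,solvent_leg `free_energy_result`s for the two legs,
#'   computed with the same estimator
#' @return a `cycle_result`
#' @export
thermo_cycle <- function(complex_leg, solvent_leg) {
  stopifnot(inherits(complex_leg, "free_energy_result"),
            inherits(solvent_leg, "free_energy_result"))
  if (!identical(complex_leg$estimator, solvent_leg$estimator)) {
    stop("legs were computed with different estimators", call. = FALSE)
  }
  ddg <- complex_leg$delta_g - solvent_leg$delta_g
  sem <- sqrt(complex_leg$sem^2 + solvent_leg$sem^2)
  structure(list(ddg = ddg, sem = sem, complex_leg = complex_leg,
                 solvent_leg = solvent_leg,
                 estimator = complex_leg$estimator),
            class = "cycle_result")
}

#' @export
print.cycle_result <- function(x, ...) {
  cat(sprintf("%s cycle: ddG = %.4f +/- %.4f kcal/mol\n", x$estimator,
              x$ddg, x$sem))
  invisible(x)
}
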