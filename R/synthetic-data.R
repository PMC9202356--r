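# Synthetic sample generators: stand-ins for MD trajectories with the
# statistical structure the ensemble analysis assumes (per-window replica
# ensembles, autocorrelation, rare-event multimodality, soft-core end-state
# curvature). Every generator emits a sample_set: per window and replica, the
# gradient du/dlambda plus the K-column cross-evaluated reduced-potential
# matrix, with a manifest recording every derived seed.

GENERATOR_VERSION <- "alchemr-gen-1"

#' Generator specification
#'
#' Describes one synthetic sampling run: the system, the per-window sample
#' count and replica count, the master seed, and optional lag-1
#' autocorrelation. The default geometry (13 windows x 5 replicas x 1000
#' samples per window) mirrors the standard ensemble protocol of five replica
#' simulations per state with samples every 4 ps over 4 ns.
#'
#' @param system a [gaussian_chain_system()] or [toy_lj_system()]
#' @param n_samples samples per window per replica (>= 2)
#' @param n_replicas replica count (>= 1)
#' @param seed master seed; replica/window streams derive from it by a fixed
#'   counter scheme so that distinct replicas get distinct streams
#' @param autocorr_rho lag-1 AR(1) correlation in \[0, 1)
#' @param leg_label `"solvent"` or `"complex"`
#' @return a `generator_spec` object
#' @export
generator_spec <- function(system, n_samples = 1000, n_replicas = 5,
                           seed = 1, autocorr_rho = 0,
                           leg_label = c("solvent", "complex")) {
  leg_label <- match.arg(leg_label)
  stopifnot(n_replicas >= 1, n_samples >= 2,
            autocorr_rho >= 0, autocorr_rho < 1)
  structure(list(system = system, n_samples = as.integer(n_samples),
                 n_replicas = as.integer(n_replicas), seed = as.integer(seed),
                 autocorr_rho = autocorr_rho, leg_label = leg_label),
            class = "generator_spec")
}

# counter scheme for derived per-(window, replica) seeds; kept below 2^31
derive_seed <- function(master, window, replica, n_replicas) {
  (as.numeric(master) * 1009 + (window - 1) * n_replicas + (replica - 1)) %%
    2147483647
}

new_sample_set <- function(windows, schedule, beta, leg_label, n_replicas,
                           manifest) {
  structure(list(windows = windows, schedule = schedule, beta = beta,
                 leg_label = leg_label, n_replicas = as.integer(n_replicas),
                 n_states = length(windows), manifest = manifest),
            class = "sample_set")
}

#' @export
print.sample_set <- function(x, ...) {
  n <- length(x$windows[[1]][[1]]$dudl)
  cat("sample_set:", x$n_states, "windows x", x$n_replicas, "replicas x",
      n, "samples, leg =", x$leg_label,
      ", generator =", x$manifest$generator, "\n")
  invisible(x)
}

# standardised AR(1) innovations-to-series filter: unit marginal variance
ar1_filter <- function(z, rho) {
  if (rho == 0) return(z)
  y <- stats::filter(z * sqrt(1 - rho^2), rho, method = "recursive",
                     init = z[1])
  as.numeric(y)
}

#' Sample a Gaussian chain
#'
#' Draws, for each window k and replica r, `n_samples` values from state k's
#' Gaussian (exact sampling, optionally AR(1)-correlated with preserved
#' marginal), and records the analytic gradient du/dlambda together with the
#' full K-column cross-evaluated reduced-potential matrix.
#'
#' @param spec a [generator_spec()] whose system is a Gaussian chain
#' @return a `sample_set`
#' @export
sample_gaussian_chain <- function(spec) {
  stopifnot(inherits(spec, "generator_spec"),
            inherits(spec$system, "gaussian_chain"))
  sys <- spec$system
  K <- sys$n_states
  schedule <- build_lambda_schedule(K, lambdas = sys$lambdas)
  seeds <- matrix(0, K, spec$n_replicas)
  windows <- vector("list", K)
  for (k in seq_len(K)) {
    reps <- vector("list", spec$n_replicas)
    sdk <- 1 / sqrt(sys$force_constants[k])
    for (r in seq_len(spec$n_replicas)) {
      seeds[k, r] <- derive_seed(spec$seed, k, r, spec$n_replicas)
      set.seed(seeds[k, r])
      z <- stats::rnorm(spec$n_samples)
      z <- ar1_filter(z, spec$autocorr_rho)
      x <- sys$centers[k] + sdk * z
      reps[[r]] <- list(x = x,
                        dudl = gaussian_chain_dudl(sys, x, k),
                        u_cross = gaussian_chain_u_cross(sys, x),
                        times = seq_along(x))
    }
    windows[[k]] <- reps
  }
  manifest <- list(generator = "gaussian_chain", version = GENERATOR_VERSION,
                   master_seed = spec$seed, derived_seeds = seeds,
                   n_samples = spec$n_samples, n_replicas = spec$n_replicas,
                   autocorr_rho = spec$autocorr_rho,
                   system = sys$endpoints, n_states = K)
  new_sample_set(windows, schedule, beta = 1, leg_label = spec$leg_label,
                 n_replicas = spec$n_replicas, manifest = manifest)
}

#' Impose AR(1) autocorrelation on a series
#'
#' Rebuilds the series as a stationary AR(1) process driven by the
#' standardised input values as innovations, then restores the input's sample
#' mean and variance. With `rho = 0` (and the same seed convention) the input
#' is returned unchanged.
#'
#' @param series numeric vector
#' @param rho lag-1 correlation in \[0, 1)
#' @param seed unused for the deterministic filter; accepted for interface
#'   stability
#' @return numeric vector with the same mean and variance, lag-1
#'   autocorrelation approximately `rho`
#' @export
add_autocorrelation <- function(series, rho, seed = NULL) {
  if (rho >= 1 || rho < 0) stop("rho must lie in [0, 1)", call. = FALSE)
  if (rho == 0) return(series)
  m <- mean(series); s <- stats::sd(series)
  if (s == 0) return(series)
  z <- (series - m) / s
  y <- ar1_filter(z, rho)
  # restore the exact sample moments
  m + s * (y - mean(y)) / stats::sd(y)
}

#' Sample a slow mode-switching mixture chain
#'
#' The rare-event generator: each window's equilibrium distribution is a
#' two-mode Gaussian mixture (modes separated in configuration space, the
#' second mode offset in reduced energy by `mode_gap * lambda_k`), and each
#' replica explores it with a two-state Markov chain over the modes with a
#' per-step switch probability. At `mode_switch_prob = 1` the chain mixes
#' rapidly and replicas agree; at very small switch probabilities each replica
#' is effectively trapped in its initial mode, reproducing the regime where
#' single-trajectory error estimates fail while the across-replica ensemble
#' spread reveals the true uncertainty. Exact per-window free energies of the
#' full mixture remain available in closed form.
#'
#' @param spec a [generator_spec()] whose system is a Gaussian chain (its
#'   force-constant interpolation sets the mode widths)
#' @param mode_gap reduced-energy offset of the second mode at lambda = 1
#' @param mode_switch_prob per-step probability of attempting a mode switch,
#'   in (0, 1\]
#' @param mode_separation distance between the two mode centers, in units of
#'   the mode standard deviation at lambda = 0
#' @return a `sample_set`; its manifest carries `analytic_f`, the closed-form
#'   relative reduced free energies of the mixture at each window
#' @export
sample_slow_switch_mixture <- function(spec, mode_gap = 2,
                                       mode_switch_prob = 1e-4,
                                       mode_separation = 6) {
  stopifnot(inherits(spec, "generator_spec"),
            inherits(spec$system, "gaussian_chain"),
            mode_switch_prob > 0, mode_switch_prob <= 1)
  sys <- spec$system
  K <- sys$n_states
  lam <- sys$lambdas
  schedule <- build_lambda_schedule(K, lambdas = lam)
  sd0 <- 1 / sqrt(sys$kf_fun(0))
  muA <- -mode_separation * sd0 / 2
  muB <- +mode_separation * sd0 / 2
  kf <- sys$force_constants
  # mixture reduced potential at state k:
  #   u_k(x) = -log( exp(-kf_k (x-muA)^2/2) + exp(-kf_k (x-muB)^2/2 - g lam_k) )
  mix_u <- function(x, k) {
    ea <- -0.5 * kf[k] * (x - muA)^2
    eb <- -0.5 * kf[k] * (x - muB)^2 - mode_gap * lam[k]
    mx <- pmax(ea, eb)
    -(mx + log(exp(ea - mx) + exp(eb - mx)))
  }
  # du/dlambda at window k: conditional mode weights times per-mode du/dl
  dlam_kf <- sys$dkf_fun(lam)
  mix_dudl <- function(x, k) {
    ea <- -0.5 * kf[k] * (x - muA)^2
    eb <- -0.5 * kf[k] * (x - muB)^2 - mode_gap * lam[k]
    mx <- pmax(ea, eb)
    wa <- exp(ea - mx); wb <- exp(eb - mx)
    tot <- wa + wb
    dA <- 0.5 * dlam_kf[k] * (x - muA)^2
    dB <- 0.5 * dlam_kf[k] * (x - muB)^2 + mode_gap
    (wa * dA + wb * dB) / tot
  }
  # closed-form relative free energies of the mixture
  zA <- sqrt(2 * pi / kf)
  zB <- zA * exp(-mode_gap * lam)
  analytic_f <- -log(zA + zB)
  analytic_f <- analytic_f - analytic_f[1]

  seeds <- matrix(0, K, spec$n_replicas)
  windows <- vector("list", K)
  for (k in seq_len(K)) {
    piB <- zB[k] / (zA[k] + zB[k])
    sdk <- 1 / sqrt(kf[k])
    reps <- vector("list", spec$n_replicas)
    for (r in seq_len(spec$n_replicas)) {
      seeds[k, r] <- derive_seed(spec$seed + 499979, k, r, spec$n_replicas)
      set.seed(seeds[k, r])
      n <- spec$n_samples
      mode <- integer(n)
      mode[1] <- stats::rbinom(1, 1, piB)          # 1 = mode B
      # Metropolis switch moves: attempt with prob p, accept by mode weight
      att <- stats::runif(n) < mode_switch_prob
      acc <- stats::runif(n)
      ratioAB <- exp(-mode_gap * lam[k])           # piB/piA
      for (t in 2:n) {
        m <- mode[t - 1]
        if (att[t]) {
          a <- if (m == 0) min(1, ratioAB) else min(1, 1 / ratioAB)
          if (acc[t] < a) m <- 1 - m
        }
        mode[t] <- m
      }
      x <- stats::rnorm(n, ifelse(mode == 1, muB, muA), sdk)
      u_cross <- vapply(seq_len(K), function(j) mix_u(x, j), numeric(n))
      reps[[r]] <- list(x = x, dudl = mix_dudl(x, k), u_cross = u_cross,
                        times = seq_len(n), mode = mode)
    }
    windows[[k]] <- reps
  }
  manifest <- list(generator = "slow_switch_mixture",
                   version = GENERATOR_VERSION,
                   master_seed = spec$seed, derived_seeds = seeds,
                   n_samples = spec$n_samples, n_replicas = spec$n_replicas,
                   mode_gap = mode_gap, mode_switch_prob = mode_switch_prob,
                   mode_separation = mode_separation,
                   analytic_f = analytic_f, n_states = K)
  new_sample_set(windows, schedule, beta = 1, leg_label = spec$leg_label,
                 n_replicas = spec$n_replicas, manifest = manifest)
}

#' Metropolis sampling of the toy Lennard-Jones system
#'
#' Runs, per window and replica, a Metropolis random-walk chain over the
#' mobile particle's position in the periodic box, with the window's soft-core
#' coupling taken from the schedule. The step size is auto-tuned during the
#' discard phase toward a target acceptance rate and frozen before
#' production. Gradients with respect to the global lambda and (optionally)
#' the full cross-evaluated reduced-potential matrix are recorded.
#'
#' @param spec a [generator_spec()] whose system is a [toy_lj_system()]
#' @param lam_schedule a [build_lambda_schedule()] schedule
#' @param n_discard equilibration steps discarded (also the tuning phase)
#' @param target_acceptance tuning target for the acceptance rate
#' @param store_u_cross logical; set `FALSE` to skip the K-column
#'   cross-evaluation (thermodynamic-integration-only runs)
#' @return a `sample_set` (`beta` attached; gradients in reduced units)
#' @export
metropolis_toy_lj <- function(spec, lam_schedule, n_discard = 400,
                              target_acceptance = 0.4, store_u_cross = TRUE) {
  stopifnot(inherits(spec, "generator_spec"), inherits(spec$system, "toy_lj"),
            inherits(lam_schedule, "lambda_schedule"))
  sys <- spec$system
  K <- lam_schedule$n_states
  beta <- sys$beta
  s_k <- toy_lj_coupling(sys, lam_schedule)
  # ds/dlambda of the coupling column (linear ramps; end intervals one-sided)
  ds <- diff(s_k) / diff(lam_schedule$lambdas)
  ds_dlambda <- c(ds[1], (ds[-length(ds)] + ds[-1]) / 2, ds[length(ds)])
  L <- sys$box_length
  seeds <- matrix(0, K, spec$n_replicas)
  windows <- vector("list", K)
  for (k in seq_len(K)) {
    s <- s_k[k]
    reps <- vector("list", spec$n_replicas)
    for (r in seq_len(spec$n_replicas)) {
      seeds[k, r] <- derive_seed(spec$seed + 900001, k, r, spec$n_replicas)
      set.seed(seeds[k, r])
      x <- stats::runif(3, 0, L)
      u_cur <- beta * toy_lj_energy(sys, x, s)
      step <- sys$sigma / 2
      n_acc <- 0; n_try <- 0; block_acc <- 0
      # tuning/discard phase
      for (t in seq_len(n_discard)) {
        xp <- (x + stats::runif(3, -step, step)) %% L
        up <- beta * toy_lj_energy(sys, xp, s)
        n_try <- n_try + 1
        if (stats::runif(1) < exp(u_cur - up)) {
          x <- xp; u_cur <- up; n_acc <- n_acc + 1; block_acc <- block_acc + 1
        }
        if (t %% 100 == 0) {     # crude proportional tuning
          rate <- block_acc / 100
          step <- step * exp(rate - target_acceptance)
          step <- min(step, L / 2)
          block_acc <- 0
        }
      }
      if (n_acc == 0 && s > 0) {
        stop("metropolis_toy_lj: zero acceptance during equilibration in window ",
             k, call. = FALSE)
      }
      # production with frozen step
      n <- spec$n_samples
      pos <- matrix(0, n, 3)
      prod_acc <- 0
      for (t in seq_len(n)) {
        xp <- (x + stats::runif(3, -step, step)) %% L
        up <- beta * toy_lj_energy(sys, xp, s)
        if (stats::runif(1) < exp(u_cur - up)) {
          x <- xp; u_cur <- up; prod_acc <- prod_acc + 1
        }
        pos[t, ] <- x
      }
      # vectorised post-evaluation over stored positions
      rdist <- vapply(seq_len(n), function(t) {
        toy_lj_distances(sys, pos[t, ])
      }, numeric(nrow(sys$fixed_coords)))
      rdist <- matrix(rdist, nrow = nrow(sys$fixed_coords))
      dudl <- beta * ds_dlambda[k] *
        colSums(matrix(softcore_lj_dlambda(rdist, s, sys$epsilon, sys$sigma,
                                           sys$softcore),
                       nrow = nrow(rdist)))
      u_cross <- NULL
      if (store_u_cross) {
        u_cross <- vapply(seq_len(K), function(j) {
          if (s_k[j] == 0) return(numeric(n))
          beta * colSums(matrix(softcore_lj_energy(rdist, s_k[j], sys$epsilon,
                                                   sys$sigma, sys$softcore),
                                nrow = nrow(rdist)))
        }, numeric(n))
      }
      reps[[r]] <- list(x = pos, dudl = dudl, u_cross = u_cross,
                        times = seq_len(n),
                        acceptance_rate = prod_acc / n, step_size = step)
    }
    windows[[k]] <- reps
  }
  manifest <- list(generator = "metropolis_toy_lj",
                   version = GENERATOR_VERSION,
                   master_seed = spec$seed, derived_seeds = seeds,
                   n_samples = spec$n_samples, n_replicas = spec$n_replicas,
                   softcore = unclass(sys$softcore), direction = sys$direction,
                   n_states = K)
  new_sample_set(windows, schedule = lam_schedule, beta = beta,
                 leg_label = spec$leg_label, n_replicas = spec$n_replicas,
                 manifest = manifest)
}
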