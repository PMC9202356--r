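# Alchemical model layer: states, lambda schedules, soft-core potentials and
# analytic reference systems with closed-form free energies.

#' Boltzmann constant in kcal/(mol K)
#'
#' @export
kB_KCAL <- 0.0019872041

#' Soft-core Lennard-Jones parameter set
#'
#' Parameters of the lambda-modified Lennard-Jones form used to remove the
#' r -> 0 singularity at intermediate coupling: `alpha` is the dimensionless
#' softness, `a` the exponent of the lambda prefactor, `b` the exponent of the
#' (1 - lambda) term inside the core, and `c` the radial exponent. The
#' conventional parameter sets are alpha = 0.5, a = 1, b = 1 with c = 6
#' (OpenMMTools default) or c = 2 (NAMD default).
#'
#' @param alpha softness, >= 0
#' @param a lambda-prefactor exponent, >= 0
#' @param b (1 - lambda) exponent, >= 0
#' @param c radial exponent; 2 and 6 are the supported conventions, other
#'   values are accepted with a warning
#' @return an object of class `softcore_params`
#' @export
softcore_params <- function(alpha = 0.5, a = 1, b = 1, c = 6) {
  stopifnot(is.numeric(alpha), length(alpha) == 1, alpha >= 0,
            is.numeric(a), a >= 0, is.numeric(b), b >= 0)
  if (!c %in% c(2, 6)) {
    warning("radial exponent c = ", c, " is outside the usual {2, 6} conventions")
  }
  structure(list(alpha = alpha, a = a, b = b, c = c), class = "softcore_params")
}

#' Soft-core Lennard-Jones pair energy
#'
#' U(r, lambda) = 4 eps lambda^a \[ (alpha (1-lambda)^b + (r/sigma)^c)^(-12/c)
#'   - (alpha (1-lambda)^b + (r/sigma)^c)^(-6/c) \].
#' At lambda = 1 this is the standard 12-6 potential; at lambda = 0 the pair is
#' fully decoupled (zero energy); for lambda < 1 and alpha > 0 the energy is
#' finite at r = 0.
#'
#' @param r pair distance (> 0); vectorised
#' @param lam coupling in \[0, 1\]
#' @param epsilon well depth (kcal/mol)
#' @param sigma zero-crossing distance
#' @param sc a [softcore_params()] object
#' @return energy in the units of `epsilon`
#' @export
softcore_lj_energy <- function(r, lam, epsilon = 1, sigma = 1,
                               sc = softcore_params()) {
  if (any(r <= 0)) stop("pair distance r must be positive", call. = FALSE)
  if (epsilon <= 0) stop("epsilon must be positive", call. = FALSE)
  if (sigma <= 0) stop("sigma must be positive", call. = FALSE)
  if (any(lam < 0 | lam > 1)) stop("lam must lie in [0, 1]", call. = FALSE)
  A <- sc$alpha * (1 - lam)^sc$b + (r / sigma)^sc$c
  4 * epsilon * lam^sc$a * (A^(-12 / sc$c) - A^(-6 / sc$c))
}

#' Analytic lambda-derivative of the soft-core Lennard-Jones energy
#'
#' Closed-form derivative of [softcore_lj_energy()] with respect to the
#' coupling `lam`; this is the per-pair contribution to du/dlambda used by
#' thermodynamic integration.
#'
#' @inheritParams softcore_lj_energy
#' @return energy per unit lambda
#' @export
softcore_lj_dlambda <- function(r, lam, epsilon = 1, sigma = 1,
                                sc = softcore_params()) {
  if (any(r <= 0)) stop("pair distance r must be positive", call. = FALSE)
  if (epsilon <= 0) stop("epsilon must be positive", call. = FALSE)
  if (sigma <= 0) stop("sigma must be positive", call. = FALSE)
  if (any(lam < 0 | lam > 1)) stop("lam must lie in [0, 1]", call. = FALSE)
  a <- sc$a; b <- sc$b; cc <- sc$c; al <- sc$alpha
  A <- al * (1 - lam)^b + (r / sigma)^cc
  bracket <- A^(-12 / cc) - A^(-6 / cc)
  # d bracket / dA, times dA/dlam = -alpha b (1-lam)^(b-1)
  dA <- -al * b * (1 - lam)^(b - 1)
  dbracket <- (-12 / cc) * A^(-12 / cc - 1) - (-6 / cc) * A^(-6 / cc - 1)
  # prefactor term a lam^(a-1); R's 0^0 = 1 handles the a = 1, lam = 0 case
  pref <- a * lam^(a - 1)
  4 * epsilon * (pref * bracket + lam^a * dbracket * dA)
}

#' Alchemical thermodynamic state
#'
#' One fixed point of the coupling path: a window index, the global lambda,
#' and the thermodynamic conditions defining the reduced potential. `beta` is
#' 1/(kB T) in mol/kcal.
#'
#' @param index 0-based window index
#' @param lambda_global global coupling in \[0, 1\]
#' @param temperature kelvin
#' @param pressure optional, atm (NPT); requires a volume when reducing
#' @param topology_mode `"annihilate"` (intra- and intermolecular terms
#'   extinguished) or `"decouple"` (intermolecular only)
#' @return an `alchemical_state` object with `beta` attached
#' @export
alchemical_state <- function(index, lambda_global, temperature = 300,
                             pressure = NULL,
                             topology_mode = c("annihilate", "decouple")) {
  topology_mode <- match.arg(topology_mode)
  stopifnot(temperature > 0, lambda_global >= 0, lambda_global <= 1, index >= 0)
  structure(list(index = as.integer(index),
                 lambda_global = lambda_global,
                 temperature = temperature,
                 beta = 1 / (kB_KCAL * temperature),
                 pressure = pressure,
                 topology_mode = topology_mode),
            class = "alchemical_state")
}

# pressure-volume conversion: atm * nm^3 per molecule -> kcal/mol
PV_KCAL_PER_ATM_NM3 <- 0.0145839

#' Reduced potential of a configuration
#'
#' u = beta (U + p V + ...): the dimensionless energy defining the sampling
#' distribution of a state. Without a pressure the NVT form beta U is
#' returned; with both pressure (atm) and volume (nm^3) the pV work term is
#' added.
#'
#' @param energy potential energy U, kcal/mol (vectorised)
#' @param state an [alchemical_state()]
#' @param volume optional instantaneous volume in nm^3
#' @return dimensionless reduced potential
#' @export
reduced_potential <- function(energy, state, volume = NULL) {
  stopifnot(inherits(state, "alchemical_state"), state$beta > 0)
  pv <- 0
  if (!is.null(state$pressure)) {
    if (is.null(volume)) {
      stop("state has a pressure but no volume was supplied", call. = FALSE)
    }
    pv <- state$pressure * volume * PV_KCAL_PER_ATM_NM3
  }
  state$beta * (energy + pv)
}

#' Build a lambda schedule
#'
#' Maps a uniform global lambda grid on \[0, 1\] to per-interaction-class
#' scaling factors for the four classes (disappearing/appearing x
#' electrostatics/van der Waals). Two conventions are supported:
#'
#' * `"two_step"` (annihilation-style): the first half of the path removes the
#'   outgoing electrostatics (1 -> 0) while growing the incoming vdW
#'   (0 -> 1); the second half removes the outgoing vdW and grows the
#'   incoming electrostatics. At global lambda = 1/2 both electrostatic
#'   classes are exactly off.
#' * `"one_step"` (decoupling-style): all four classes scale over the full
#'   interval, electrostatics at a faster pace: the outgoing electrostatics
#'   reach zero at global lambda = `elec_pace` and the incoming ones switch on
#'   only from `1 - elec_pace`, while vdW scales linearly throughout.
#'
#' @param n_states number of states K >= 2
#' @param scheme `"one_step"` or `"two_step"`
#' @param elec_pace fraction of the path over which electrostatics complete in
#'   the one-step scheme (default 0.5)
#' @param lambdas optional non-uniform global lambda grid overriding the
#'   uniform default (must start at 0, end at 1, strictly increasing)
#' @return a `lambda_schedule` with components `lambdas` (global grid) and
#'   `factors` (K x 4 matrix with columns elec_dis, vdw_dis, elec_app, vdw_app)
#' @export
build_lambda_schedule <- function(n_states = 13,
                                  scheme = c("one_step", "two_step"),
                                  elec_pace = 0.5, lambdas = NULL) {
  scheme <- match.arg(scheme)
  if (n_states < 2) stop("a schedule needs at least 2 states", call. = FALSE)
  if (is.null(lambdas)) {
    lambdas <- seq(0, 1, length.out = n_states)
  } else {
    if (length(lambdas) != n_states || lambdas[1] != 0 ||
        lambdas[n_states] != 1 || any(diff(lambdas) <= 0)) {
      stop("lambdas must be strictly increasing from 0 to 1 with length n_states",
           call. = FALSE)
    }
  }
  lam <- lambdas
  if (scheme == "two_step") {
    elec_dis <- pmax(0, 1 - 2 * lam)
    vdw_app  <- pmin(1, 2 * lam)
    vdw_dis  <- pmin(1, 2 - 2 * lam)
    elec_app <- pmax(0, 2 * lam - 1)
  } else {
    stopifnot(elec_pace > 0, elec_pace <= 1)
    elec_dis <- pmax(0, 1 - lam / elec_pace)
    elec_app <- pmax(0, (lam - (1 - elec_pace)) / elec_pace)
    elec_app <- pmin(1, elec_app)
    vdw_dis  <- 1 - lam
    vdw_app  <- lam
  }
  factors <- cbind(elec_dis = elec_dis, vdw_dis = vdw_dis,
                   elec_app = elec_app, vdw_app = vdw_app)
  structure(list(lambdas = lam, factors = factors, scheme = scheme,
                 n_states = as.integer(n_states), elec_pace = elec_pace),
            class = "lambda_schedule")
}

#' @export
print.lambda_schedule <- function(x, ...) {
  cat("lambda schedule (", x$scheme, "), K = ", x$n_states, "\n", sep = "")
  print(round(cbind(lambda = x$lambdas, x$factors), 4))
  invisible(x)
}

#' Gaussian chain reference system
#'
#' A chain of K harmonic (Gaussian) states whose reduced potential at state k
#' is u_k(x) = K_k (x - mu_k)^2 / 2 + c_k, with K_k, mu_k, c_k obtained from
#' smooth interpolations along the global lambda. Its reduced free energy is
#' known in closed form, f_k = -log(2 pi / K_k)/2 + c_k, which makes the chain
#' an exact oracle for every estimator in the package.
#'
#' Endpoint values are interpolated smoothly: force constants log-linearly in
#' lambda (guaranteeing positivity), centers and offsets linearly.
#'
#' @param n_states number of states K
#' @param kf force-constant endpoints c(K_0, K_1) in reduced energy/length^2
#' @param mu center endpoints (length units)
#' @param offset reduced-energy offset endpoints
#' @param lambdas optional explicit global lambda grid
#' @return a `gaussian_chain` system object carrying per-state parameter
#'   vectors and the interpolating functions with their analytic derivatives
#' @export
gaussian_chain_system <- function(n_states = 13, kf = c(1, 4), mu = c(0, 1),
                                  offset = c(0, 0), lambdas = NULL) {
  stopifnot(length(kf) == 2, all(kf > 0), length(mu) == 2, length(offset) == 2,
            n_states >= 2)
  if (is.null(lambdas)) lambdas <- seq(0, 1, length.out = n_states)
  lkr <- log(kf[2] / kf[1])
  kf_fun  <- function(l) kf[1] * exp(l * lkr)
  dkf_fun <- function(l) kf[1] * exp(l * lkr) * lkr
  mu_fun  <- function(l) mu[1] + l * (mu[2] - mu[1])
  dmu_fun <- function(l) rep(mu[2] - mu[1], length(l))
  c_fun   <- function(l) offset[1] + l * (offset[2] - offset[1])
  dc_fun  <- function(l) rep(offset[2] - offset[1], length(l))
  structure(list(n_states = as.integer(n_states), lambdas = lambdas,
                 force_constants = kf_fun(lambdas), centers = mu_fun(lambdas),
                 offsets = c_fun(lambdas),
                 kf_fun = kf_fun, dkf_fun = dkf_fun,
                 mu_fun = mu_fun, dmu_fun = dmu_fun,
                 c_fun = c_fun, dc_fun = dc_fun,
                 endpoints = list(kf = kf, mu = mu, offset = offset)),
            class = "gaussian_chain")
}

#' Closed-form per-state reduced free energies of a Gaussian chain
#'
#' f_k = -log(2 pi / K_k)/2 + c_k, reported relative to state 0 (f_0 = 0).
#' Centers do not enter: the Gaussian partition function is translation
#' invariant.
#'
#' @param system a [gaussian_chain_system()]
#' @return numeric vector of K relative reduced free energies
#' @export
gaussian_chain_analytic <- function(system) {
  stopifnot(inherits(system, "gaussian_chain"))
  if (any(system$force_constants <= 0)) {
    stop("force constants must be positive", call. = FALSE)
  }
  f <- -0.5 * log(2 * pi / system$force_constants) + system$offsets
  f - f[1]
}

# reduced potential of every chain state evaluated at positions x: n x K
gaussian_chain_u_cross <- function(system, x) {
  K <- system$n_states
  out <- matrix(0, length(x), K)
  for (k in seq_len(K)) {
    out[, k] <- 0.5 * system$force_constants[k] * (x - system$centers[k])^2 +
      system$offsets[k]
  }
  out
}

# analytic du/dlambda of the chain at window k for positions x
gaussian_chain_dudl <- function(system, x, k) {
  l <- system$lambdas[k]
  kf <- system$kf_fun(l); dkf <- system$dkf_fun(l)
  mu <- system$mu_fun(l); dmu <- system$dmu_fun(l)
  dc <- system$dc_fun(l)
  0.5 * dkf * (x - mu)^2 - kf * (x - mu) * dmu + dc
}

#' Toy Lennard-Jones system
#'
#' A single mobile particle in a periodic cubic box interacting with fixed
#' neighbors through the soft-core Lennard-Jones potential. The mobile
#' particle is alchemically appearing or disappearing; the coupling applied in
#' window k is the schedule's vdW factor for that direction. Minimal system
#' exhibiting the end-state gradient curvature that distinguishes soft-core
#' parameterisations.
#'
#' @param epsilon well depth, kcal/mol
#' @param sigma LJ length unit
#' @param box_length cubic box edge (> 2 sigma)
#' @param fixed_coords matrix (n x 3) of fixed-particle coordinates; defaults
#'   to one particle at the box center
#' @param softcore a [softcore_params()]
#' @param direction `"disappearing"` or `"appearing"`
#' @param temperature kelvin
#' @return a `toy_lj` system object
#' @export
toy_lj_system <- function(epsilon = 0.5, sigma = 1, box_length = 4,
                          fixed_coords = NULL,
                          softcore = softcore_params(alpha = 0.5, c = 2),
                          direction = c("disappearing", "appearing"),
                          temperature = 300) {
  direction <- match.arg(direction)
  stopifnot(epsilon > 0, sigma > 0, box_length > 2 * sigma)
  if (is.null(fixed_coords)) {
    fixed_coords <- matrix(box_length / 2, 1, 3)
  }
  fixed_coords <- as.matrix(fixed_coords)
  stopifnot(ncol(fixed_coords) == 3)
  structure(list(epsilon = epsilon, sigma = sigma, box_length = box_length,
                 fixed_coords = fixed_coords, softcore = softcore,
                 direction = direction, temperature = temperature,
                 beta = 1 / (kB_KCAL * temperature)),
            class = "toy_lj")
}

# minimum-image distances from position x (length-3) to all fixed particles
toy_lj_distances <- function(system, x) {
  d <- sweep(system$fixed_coords, 2, x)
  d <- d - system$box_length * round(d / system$box_length)
  sqrt(rowSums(d^2))
}

# coupling factor for the system's direction at each schedule state
toy_lj_coupling <- function(system, schedule) {
  col <- if (system$direction == "disappearing") "vdw_dis" else "vdw_app"
  schedule$factors[, col]
}

# potential energy (kcal/mol) of the mobile particle at coupling s
toy_lj_energy <- function(system, x, s) {
  if (s == 0) return(0)
  r <- toy_lj_distances(system, x)
  sum(softcore_lj_energy(r, s, system$epsilon, system$sigma, system$softcore))
}

# dU/d(global lambda) = dU/ds * ds/dlambda (kcal/mol per unit lambda)
toy_lj_dudl <- function(system, x, s, ds_dlambda) {
  r <- toy_lj_distances(system, x)
  sum(softcore_lj_dlambda(r, s, system$epsilon, system$sigma, system$softcore)) *
    ds_dlambda
}

#' Deterministic gradient profile of the toy LJ system
#'
#' Per-window expectation of du/dlambda computed by midpoint quadrature of
#' the Boltzmann average over a 3-D grid spanning the box. Serves as the
#' exact reference against which the Metropolis sampler and the trapezoid TI
#' quadrature bias are judged (e.g. a dense-grid TI value from a 129-window
#' schedule).
#'
#' @param system a [toy_lj_system()]
#' @param schedule a [build_lambda_schedule()] schedule
#' @param ngrid grid points per box dimension
#' @return per-window expected reduced gradient (length K)
#' @export
toy_lj_exact_gradient <- function(system, schedule, ngrid = 48) {
  stopifnot(inherits(system, "toy_lj"))
  s_k <- toy_lj_coupling(system, schedule)
  ds <- diff(s_k) / diff(schedule$lambdas)
  ds_dlambda <- c(ds[1], (ds[-length(ds)] + ds[-1]) / 2, ds[length(ds)])
  L <- system$box_length
  g <- seq(L / (2 * ngrid), L - L / (2 * ngrid), length.out = ngrid)
  gr <- as.matrix(expand.grid(g, g, g))
  # minimum-image distances to every fixed particle
  rmat <- vapply(seq_len(nrow(system$fixed_coords)), function(j) {
    d <- sweep(gr, 2, system$fixed_coords[j, ])
    d <- d - L * round(d / L)
    sqrt(rowSums(d^2))
  }, numeric(nrow(gr)))
  beta <- system$beta
  vapply(seq_along(s_k), function(k) {
    s <- s_k[k]
    if (s == 0) {
      u <- numeric(nrow(gr))
    } else {
      u <- beta * rowSums(matrix(
        softcore_lj_energy(rmat, s, system$epsilon, system$sigma,
                           system$softcore), nrow = nrow(gr)))
    }
    du <- beta * rowSums(matrix(
      softcore_lj_dlambda(rmat, s, system$epsilon, system$sigma,
                          system$softcore), nrow = nrow(gr))) * ds_dlambda[k]
    w <- exp(-u)
    sum(w * du) / sum(w)
  }, numeric(1))
}
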