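# Uncertainty quantification: ensemble bootstrap, trapezoid error propagation
# for TI, the analytic MBAR covariance estimator, the ensemble-vs-analytic
# error comparison, and statistical-inefficiency/de-correlation utilities.

#' Bootstrap a set of replica estimates
#'
#' Resamples the replica values with replacement, returning the bootstrap
#' mean, the SEM (standard deviation of the bootstrap means) and a
#' percentile confidence interval.
#'
#' @param values replica estimates
#' @param n_boot number of resamples (>= 100)
#' @param seed RNG seed
#' @param level confidence level for the percentile interval
#' @return list with `mean`, `sem`, `ci` (length 2); with a single value the
#'   SEM and CI are `NA` (flagged unavailable)
#' @export
ensemble_bootstrap <- function(values, n_boot = 5000, seed = 1, level = 0.95) {
  stopifnot(n_boot >= 100)
  R <- length(values)
  if (R < 2) {
    return(list(mean = values, sem = NA_real_, ci = c(NA_real_, NA_real_)))
  }
  set.seed(seed)
  idx <- matrix(sample.int(R, n_boot * R, replace = TRUE), n_boot, R)
  bm <- rowMeans(matrix(values[idx], n_boot, R))
  alpha <- (1 - level) / 2
  list(mean = mean(bm), sem = stats::sd(bm),
       ci = unname(stats::quantile(bm, c(alpha, 1 - alpha))))
}

#' Trapezoid quadrature weights of a lambda grid
#'
#' w_1 = dl_1/2, interior w_i = (dl_{i-1} + dl_i)/2, w_K = dl_{K-1}/2; these
#' are the coefficients with which each window mean enters the trapezoid
#' integral.
#'
#' @param lambdas strictly increasing grid
#' @return numeric weight vector
#' @export
trapezoid_weights <- function(lambdas) {
  dl <- diff(lambdas)
  K <- length(lambdas)
  c(dl[1] / 2,
    if (K > 2) (dl[-(K - 1)] + dl[-1]) / 2 else NULL,
    dl[K - 1] / 2)
}

#' Propagate per-window errors through thermodynamic integration
#'
#' For independent window means with standard errors sigma(lambda_i), the TI
#' estimate's variance is sigma_leg^2 = sum_i w_i^2 sigma_i^2 with w_i the
#' trapezoid weights of the grid ("delta lambda between adjacent windows").
#'
#' @param sigma_per_window one standard error >= 0 per window
#' @param schedule the schedule whose `lambdas` grid was integrated
#' @return sigma_leg, the propagated standard error of the TI integral
#' @export
propagate_ti_error <- function(sigma_per_window, schedule) {
  if (any(sigma_per_window < 0)) stop("negative sigma", call. = FALSE)
  w <- trapezoid_weights(schedule$lambdas)
  if (length(w) != length(sigma_per_window)) {
    stop("need one sigma per window", call. = FALSE)
  }
  sqrt(sum(w^2 * sigma_per_window^2))
}

# Moore-Penrose pseudo-inverse via SVD
pinv <- function(m, rtol = 1e-12) {
  s <- svd(m)
  keep <- s$d > max(s$d) * rtol
  s$v[, keep, drop = FALSE] %*%
    (t(s$u[, keep, drop = FALSE]) / s$d[keep])
}

# asymptotic covariance matrix of the MBAR free energies (pseudo-inverse
# formulation): with W = U S V', Theta = V S (I - S V' N V S)^+ S V'
mbar_theta <- function(W, N_k) {
  sv <- svd(W)
  V <- sv$v; d <- sv$d
  K <- ncol(W)
  inner <- diag(K) - (d * t(V)) %*% (N_k * V) %*% diag(d, K)
  V %*% diag(d, K) %*% pinv(inner) %*% (d * t(V))
}

#' Analytic MBAR standard error of a free-energy difference
#'
#' Asymptotic standard error of f_j - f_i from the converged weight matrix,
#' using the pseudo-inverse covariance estimator. Symmetric in (i, j); small
#' negative variances from roundoff are clipped to zero with a warning.
#'
#' @param W converged N x K MBAR weight matrix
#' @param N_k per-state sample counts
#' @param i,j 1-based state indices
#' @return standard error of f_j - f_i (dimensionless)
#' @export
mbar_analytic_sem <- function(W, N_k, i = 1, j = ncol(W)) {
  if (i == j) return(0)
  theta <- mbar_theta(W, N_k)
  v <- theta[i, i] + theta[j, j] - 2 * theta[i, j]
  if (v < 0) {
    warning("negative variance from roundoff clipped to 0")
    v <- 0
  }
  sqrt(v)
}

#' Statistical inefficiency of a time series
#'
#' g = 1 + 2 sum_t rho_t with the autocorrelation sum truncated at the first
#' non-positive term (initial-positive-sequence rule). The recommended
#' subsampling stride is ceiling(g).
#'
#' @param series numeric vector, length >= 10
#' @return list with `g`, `stride`
#' @export
statistical_inefficiency <- function(series) {
  n <- length(series)
  if (n < 10) stop("series too short", call. = FALSE)
  if (stats::sd(series) == 0) {
    warning("zero-variance series; statistical inefficiency set to 1")
    return(list(g = 1, stride = 1L))
  }
  ac <- stats::acf(series, lag.max = n - 2, plot = FALSE,
                   demean = TRUE)$acf[-1]
  firstneg <- which(ac <= 0)[1]
  if (!is.na(firstneg)) ac <- ac[seq_len(firstneg - 1)]
  g <- max(1, 1 + 2 * sum(ac))
  list(g = g, stride = as.integer(ceiling(g)))
}

# subsample every replica series in a sample set by its gradient-series
# statistical inefficiency
subsample_sampleset <- function(samples) {
  out <- samples
  for (k in seq_along(samples$windows)) {
    for (r in seq_along(samples$windows[[k]])) {
      rep <- samples$windows[[k]][[r]]
      stride <- statistical_inefficiency(rep$dudl)$stride
      keep <- seq(1, length(rep$dudl), by = stride)
      rep$dudl <- rep$dudl[keep]
      if (!is.null(rep$u_cross)) rep$u_cross <- rep$u_cross[keep, , drop = FALSE]
      rep$times <- rep$times[keep]
      out$windows[[k]][[r]] <- rep
    }
  }
  out
}

#' Compare ensemble-bootstrap and analytic MBAR errors
#'
#' Per replica, MBAR is solved on the replica's own samples and the analytic
#' (asymptotic) SEM of the end-to-end free energy extracted; these are
#' averaged across replicas, scaled by 1/sqrt(R) to the footing of the
#' R-replica mean, and compared with the ensemble bootstrap SEM of the
#' per-replica free-energy values. For well-mixed sampling both routes
#' estimate the same asymptotic variance and the ratio is near 1; a ratio
#' well above 1 means a single trajectory's internal error estimate
#' understates the true run-to-run variability (the rare-event regime).
#'
#' @param samples a `sample_set` with >= 2 replicas and cross-evaluations
#' @param n_boot,seed bootstrap controls
#' @param subsample logical; de-correlate each replica series by its
#'   statistical inefficiency before estimating
#' @return an `error_comparison` with per-replica analytic SEMs, their mean,
#'   the ensemble bootstrap SEM, and the ratio ensemble/analytic
#' @export
error_comparison <- function(samples, n_boot = 5000, seed = 1,
                             subsample = FALSE) {
  if (samples$n_replicas < 2) stop("need >= 2 replicas", call. = FALSE)
  if (subsample) samples <- subsample_sampleset(samples)
  R <- samples$n_replicas
  per_rep_dg <- numeric(R)
  per_rep_sem <- numeric(R)
  for (r in seq_len(R)) {
    u <- stack_replica_u(samples, r)
    N_k <- replica_N_k(samples, r)
    fit <- mbar_solve(u, N_k)
    K <- length(fit$f)
    per_rep_dg[r] <- fit$f[K] / samples$beta
    per_rep_sem[r] <- mbar_analytic_sem(fit$W, N_k, 1, K) / samples$beta
  }
  bs <- ensemble_bootstrap(per_rep_dg, n_boot = n_boot, seed = seed)
  # put both on the footing of the R-replica mean: the analytic MBAR
  # prediction of the ensemble-mean SEM is the averaged single-replica SEM
  # divided by sqrt(R) (replicas are independent)
  mean_analytic <- mean(per_rep_sem) / sqrt(R)
  ratio <- if (mean_analytic > 0) bs$sem / mean_analytic else NA_real_
  structure(list(analytic_sem_per_replica = per_rep_sem,
                 mean_analytic_sem = mean_analytic,
                 ensemble_bootstrap_sem = bs$sem,
                 per_replica_dg = per_rep_dg,
                 ratio = ratio, leg_label = samples$leg_label,
                 subsampled = subsample),
            class = "error_comparison")
}

#' @export
print.error_comparison <- function(x, ...) {
  cat(sprintf(
    "error comparison (%s%s): ensemble SEM %.4g vs analytic MBAR SEM %.4g (ratio %.2f)\n",
    x$leg_label, if (x$subsampled) ", de-correlated" else "",
    x$ensemble_bootstrap_sem, x$mean_analytic_sem, x$ratio))
  invisible(x)
}
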