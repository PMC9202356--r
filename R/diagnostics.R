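# Diagnostics: phase-space overlap matrices with the tridiagonal / 0.03
# criterion, and gradient-profile curvature metrics.

#' Phase-space overlap matrix from MBAR weights
#'
#' O_ik = N_k sum_n W_ni W_nk: the probability that a configuration sampled
#' in window i could have been drawn in window k. Row-stochastic by the
#' normalisation of the converged weights.
#'
#' @param W converged N x K MBAR weight matrix
#' @param N_k per-state sample counts
#' @param source optional metadata (leg/transformation labels)
#' @return an `overlap_matrix`
#' @export
overlap_matrix <- function(W, N_k, source = NULL) {
  K <- ncol(W)
  O <- crossprod(W)                 # sum_n W_ni W_nk
  O <- sweep(O, 2, N_k, "*")
  rs <- rowSums(O)
  if (any(abs(rs - 1) > 1e-6)) {
    stop("weight matrix does not appear converged (row sums deviate from 1)",
         call. = FALSE)
  }
  structure(list(values = O, n_states = K, replica_averaged = FALSE,
                 source = source),
            class = "overlap_matrix")
}

#' Replica-resolved and replica-averaged overlap
#'
#' Solves MBAR per replica and builds the overlap matrix of each replica's
#' weight matrix; optionally averages the matrices entrywise across replicas
#' (ensemble averaging markedly stabilises low-overlap entries).
#'
#' @param samples a `sample_set` with cross-evaluations
#' @param replica_averaged return the entrywise replica average (default) or
#'   the list of per-replica matrices
#' @return an `overlap_matrix` (averaged) or list of them
#' @export
sample_overlap <- function(samples, replica_averaged = TRUE) {
  R <- samples$n_replicas
  mats <- lapply(seq_len(R), function(r) {
    fit <- mbar_solve(stack_replica_u(samples, r), replica_N_k(samples, r))
    overlap_matrix(fit$W, replica_N_k(samples, r),
                   source = list(leg = samples$leg_label, replica = r))
  })
  if (!replica_averaged) return(mats)
  avg <- Reduce(`+`, lapply(mats, `[[`, "values")) / R
  structure(list(values = avg, n_states = samples$n_states,
                 replica_averaged = TRUE,
                 source = list(leg = samples$leg_label)),
            class = "overlap_matrix")
}

#' Check the tridiagonal overlap criterion
#'
#' Reliable perturbative estimates require the overlap matrix to be
#' effectively tridiagonal with first off-diagonal entries above a threshold
#' (0.03 by convention). Only the first off-diagonals can fail the check;
#' entries beyond them are reported but never gate the verdict.
#'
#' @param O an [overlap_matrix()]
#' @param threshold minimum acceptable first-off-diagonal overlap
#' @return list with `pass`, `failing` (data frame of offending (i, k) pairs
#'   and values, 1-based indices), `min_offdiag`
#' @export
overlap_check <- function(O, threshold = 0.03) {
  stopifnot(inherits(O, "overlap_matrix"), threshold > 0, threshold < 1)
  V <- O$values
  K <- O$n_states
  i <- seq_len(K - 1)
  up <- V[cbind(i, i + 1)]
  lo <- V[cbind(i + 1, i)]
  fail <- data.frame(i = c(i[up <= threshold], (i + 1)[lo <= threshold]),
                     k = c((i + 1)[up <= threshold], i[lo <= threshold]),
                     value = c(up[up <= threshold], lo[lo <= threshold]))
  list(pass = nrow(fail) == 0, failing = fail,
       min_offdiag = min(c(up, lo)), threshold = threshold)
}

#' Gradient profile of a sample set
#'
#' Per-window replica means of du/dlambda, their ensemble mean and SEM, and
#' curvature metrics: the raw second difference at interior windows and
#' one-sided second differences at the two end states (large end-state
#' curvature flags soft-core parameterisations that strain trapezoidal TI).
#'
#' @param samples a `sample_set`
#' @return a `gradient_profile` with `mean`, `sem`, `replica_means` (K x R),
#'   `curvature` (interior, NA at the ends), `end_state_curvature` (length 2)
#' @export
gradient_profile <- function(samples) {
  m <- replica_window_means(samples)   # K x R
  K <- nrow(m)
  if (K < 3) stop("need at least 3 windows for curvature", call. = FALSE)
  mu <- rowMeans(m)
  sem <- apply(m, 1, stats::sd) / sqrt(ncol(m))
  curv <- rep(NA_real_, K)
  curv[2:(K - 1)] <- mu[1:(K - 2)] - 2 * mu[2:(K - 1)] + mu[3:K]
  end_curv <- c(mu[1] - 2 * mu[2] + mu[3],
                mu[K] - 2 * mu[K - 1] + mu[K - 2])
  structure(list(mean = mu, sem = sem, replica_means = m,
                 curvature = curv, end_state_curvature = end_curv,
                 lambdas = samples$schedule$lambdas),
            class = "gradient_profile")
}

#' @export
print.gradient_profile <- function(x, ...) {
  cat("gradient profile over", length(x$mean), "windows; end-state curvature",
      sprintf("(%.4g, %.4g)\n", x$end_state_curvature[1],
              x$end_state_curvature[2]))
  invisible(x)
}
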