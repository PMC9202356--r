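# Shared fixtures: small synthetic systems built in code at test time.

default_chain <- function(K = 13, kf = c(1, 4), mu = c(0, 1)) {
  gaussian_chain_system(K, kf = kf, mu = mu)
}

chain_samples <- function(K = 13, n = 300, R = 5, seed = 1, kf = c(1, 4),
                          mu = c(0, 1), rho = 0) {
  sys <- gaussian_chain_system(K, kf = kf, mu = mu)
  sample_gaussian_chain(generator_spec(sys, n_samples = n, n_replicas = R,
                                       seed = seed, autocorr_rho = rho))
}

# stack all replicas of a sample set into one (u_cross, N_k) pair
pooled_u <- function(samples) {
  R <- samples$n_replicas
  u <- do.call(rbind, lapply(seq_len(R), function(r) {
    do.call(rbind, lapply(samples$windows, function(w) w[[r]]$u_cross))
  }))
  N_k <- vapply(samples$windows, function(w) {
    sum(vapply(w, function(rep) nrow(rep$u_cross), numeric(1)))
  }, numeric(1))
  list(u = u, N_k = N_k)
}

# brute-force Kendall tau-b by pair enumeration (tie-corrected)
kendall_tau_b_brute <- function(x, y) {
  n <- length(x)
  conc <- disc <- tx <- ty <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      dx <- sign(x[j] - x[i]); dy <- sign(y[j] - y[i])
      if (dx == 0 && dy == 0) next
      if (dx == 0) tx <- tx + 1
      else if (dy == 0) ty <- ty + 1
      else if (dx == dy) conc <- conc + 1
      else disc <- disc + 1
    }
  }
  (conc - disc) / sqrt((conc + disc + tx) * (conc + disc + ty))
}
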