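# Comparison statistics between ddG sets (error metrics, correlations, OLS),
# quadrature significance testing of paired estimates, and
# distribution-shape (skewness / excess kurtosis) analysis.

#' Error metrics between predicted and reference values
#'
#' MUE = mean |pred - ref|, MSE = mean (pred - ref)^2 (mean *squared* error;
#' RMSD = sqrt(MSE) holds identically).
#'
#' @param pred,ref equal-length finite numeric vectors
#' @return list with `mue`, `mse`, `rmsd`
#' @export
error_stats <- function(pred, ref) {
  if (length(pred) != length(ref)) stop("length mismatch", call. = FALSE)
  stopifnot(all(is.finite(pred)), all(is.finite(ref)))
  d <- pred - ref
  mse <- mean(d^2)
  list(mue = mean(abs(d)), mse = mse, rmsd = sqrt(mse))
}

# paired percentile bootstrap of an arbitrary paired statistic
paired_bootstrap_ci <- function(x, y, statfun, n_boot, seed, level) {
  n <- length(x)
  set.seed(seed)
  reps <- vapply(seq_len(n_boot), function(b) {
    i <- sample.int(n, n, replace = TRUE)
    statfun(x[i], y[i])
  }, numeric(length(statfun(x, y))))
  alpha <- (1 - level) / 2
  if (is.null(dim(reps))) reps <- matrix(reps, nrow = 1)
  t(apply(reps, 1, stats::quantile, probs = c(alpha, 1 - alpha),
          na.rm = TRUE))
}

#' Correlation statistics with bootstrap confidence intervals
#'
#' Pearson, Spearman, and Kendall (tau-b, tie-corrected) correlations with
#' paired percentile-bootstrap confidence intervals.
#'
#' @param x,y numeric vectors, n >= 3; ties permitted
#' @param n_boot bootstrap resamples
#' @param seed RNG seed
#' @param level confidence level
#' @return list of `pearson`, `spearman`, `kendall_tau`, each a list with
#'   `value` and `ci`
#' @export
correlation_stats <- function(x, y, n_boot = 5000, seed = 1, level = 0.95) {
  if (length(x) != length(y)) stop("length mismatch", call. = FALSE)
  if (length(x) < 3) stop("need n >= 3", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("correlations undefined for zero-variance input", call. = FALSE)
  }
  vals <- function(a, b) {
    c(stats::cor(a, b, method = "pearson"),
      stats::cor(a, b, method = "spearman"),
      stats::cor(a, b, method = "kendall"))
  }
  pt <- vals(x, y)
  ci <- suppressWarnings(
    paired_bootstrap_ci(x, y, function(a, b) {
      if (stats::sd(a) == 0 || stats::sd(b) == 0) return(rep(NA_real_, 3))
      vals(a, b)
    }, n_boot, seed, level))
  list(pearson = list(value = pt[1], ci = ci[1, ]),
       spearman = list(value = pt[2], ci = ci[2, ]),
       kendall_tau = list(value = pt[3], ci = ci[3, ]))
}

#' Ordinary least squares fit with bootstrap confidence intervals
#'
#' @param x,y numeric vectors, n >= 2, `x` not constant
#' @inheritParams correlation_stats
#' @return list of `slope` and `intercept`, each with `value` and `ci`
#' @export
linear_fit <- function(x, y, n_boot = 5000, seed = 1, level = 0.95) {
  if (length(x) != length(y)) stop("length mismatch", call. = FALSE)
  if (stats::sd(x) == 0) stop("x is constant; fit undefined", call. = FALSE)
  co <- stats::coef(stats::lm(y ~ x))
  ci <- suppressWarnings(
    paired_bootstrap_ci(x, y, function(a, b) {
      if (stats::sd(a) == 0) return(c(NA_real_, NA_real_))
      rev(stats::coef(stats::lm(b ~ a)))  # slope, intercept
    }, n_boot, seed, level))
  list(slope = list(value = unname(co[2]), ci = ci[1, ]),
       intercept = list(value = unname(co[1]), ci = ci[2, ]))
}

# moment-based sample skewness and excess kurtosis
sample_skewness <- function(v) {
  m <- mean(v); s2 <- mean((v - m)^2)
  mean((v - m)^3) / s2^1.5
}

sample_excess_kurtosis <- function(v) {
  m <- mean(v); s2 <- mean((v - m)^2)
  mean((v - m)^4) / s2^2 - 3
}

#' Distribution-shape report
#'
#' Sample skewness (m3 / m2^(3/2)) and excess kurtosis (m4 / m2^2 - 3,
#' i.e. kurtosis minus the Gaussian value of 3), with percentile-bootstrap
#' confidence intervals (90% by default). A component's normality flag is
#' set when its CI excludes 0.
#'
#' @param values numeric vector, n >= 3
#' @param n_boot bootstrap resamples
#' @param seed RNG seed
#' @param level CI level (default 0.90)
#' @return a `distribution_report`
#' @export
distribution_stats <- function(values, n_boot = 5000, seed = 1, level = 0.90) {
  n <- length(values)
  if (n < 3) stop("need n >= 3", call. = FALSE)
  if (stats::sd(values) == 0) {
    stop("shape statistics undefined for zero-variance input", call. = FALSE)
  }
  sk <- sample_skewness(values)
  ku <- sample_excess_kurtosis(values)
  set.seed(seed)
  idx <- matrix(sample.int(n, n_boot * n, replace = TRUE), n_boot, n)
  bm <- matrix(values[idx], n_boot, n)
  bsk <- apply(bm, 1, sample_skewness)
  bku <- apply(bm, 1, sample_excess_kurtosis)
  alpha <- (1 - level) / 2
  ci_sk <- unname(stats::quantile(bsk, c(alpha, 1 - alpha), na.rm = TRUE))
  ci_ku <- unname(stats::quantile(bku, c(alpha, 1 - alpha), na.rm = TRUE))
  structure(list(skewness = sk, excess_kurtosis = ku,
                 skewness_ci = ci_sk, excess_kurtosis_ci = ci_ku,
                 n = n, level = level,
                 normality_flag = c(
                   skewness = ci_sk[1] > 0 || ci_sk[2] < 0,
                   excess_kurtosis = ci_ku[1] > 0 || ci_ku[2] < 0)),
            class = "distribution_report")
}

#' @export
print.distribution_report <- function(x, ...) {
  cat(sprintf("skewness %.3f [%.3f, %.3f]; excess kurtosis %.3f [%.3f, %.3f] (n = %d)\n",
              x$skewness, x$skewness_ci[1], x$skewness_ci[2],
              x$excess_kurtosis, x$excess_kurtosis_ci[1],
              x$excess_kurtosis_ci[2], x$n))
  invisible(x)
}

#' Significance of the difference of two estimates
#'
#' delta = a - b with the combined error sigma_quad = sqrt(sem_a^2 + sem_b^2);
#' the difference is flagged significant when |delta| > z sigma_quad
#' (z = 1 by default, the working criterion for calling two estimators
#' different).
#'
#' @param est_a,sem_a first estimate and its SEM
#' @param est_b,sem_b second estimate and its SEM
#' @param z threshold multiplier
#' @return a `significance_record`
#' @export
significance_test <- function(est_a, sem_a, est_b, sem_b, z = 1) {
  stopifnot(sem_a >= 0, sem_b >= 0, z > 0)
  delta <- est_a - est_b
  sq <- sqrt(sem_a^2 + sem_b^2)
  structure(list(delta = delta, sigma_quad = sq, z = z,
                 significant = abs(delta) > z * sq),
            class = "significance_record")
}

#' @export
print.significance_record <- function(x, ...) {
  cat(sprintf("delta = %.2f(%.2f): %ssignificant at z = %g\n", x$delta,
              x$sigma_quad, if (x$significant) "" else "not ", x$z))
  invisible(x)
}

# "value[lower, upper]" presentation used in the report tables
format_ci <- function(value, ci, digits = 2) {
  sprintf("%.*f[%.*f, %.*f]", digits, value, digits, ci[1], digits, ci[2])
}

#' Full comparison report between two ddG sets
#'
#' Assembles the error metrics, the three correlations and the OLS fit, all
#' with paired-bootstrap confidence intervals, into one report comparing a
#' predicted ddG vector with a reference set.
#'
#' @param pred,ref equal-length ddG vectors (kcal/mol)
#' @param labels optional transformation labels
#' @param n_boot,seed,level bootstrap controls (95% intervals by default)
#' @return a `comparison_report`
#' @export
comparison_report <- function(pred, ref, labels = NULL, n_boot = 5000,
                              seed = 1, level = 0.95) {
  es <- error_stats(pred, ref)
  es_ci <- paired_bootstrap_ci(pred, ref, function(a, b) {
    d <- a - b
    c(mean(abs(d)), mean(d^2), sqrt(mean(d^2)))
  }, n_boot, seed, level)
  cs <- correlation_stats(pred, ref, n_boot, seed + 1, level)
  lf <- linear_fit(ref, pred, n_boot, seed + 2, level)
  structure(list(
    pairs = data.frame(label = labels %||% seq_along(pred),
                       predicted = pred, reference = ref),
    mue = list(value = es$mue, ci = es_ci[1, ]),
    mse = list(value = es$mse, ci = es_ci[2, ]),
    rmsd = list(value = es$rmsd, ci = es_ci[3, ]),
    pearson = cs$pearson, spearman = cs$spearman,
    kendall_tau = cs$kendall_tau,
    slope = lf$slope, intercept = lf$intercept,
    level = level),
    class = "comparison_report")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.comparison_report <- function(x, ...) {
  cat("comparison of", nrow(x$pairs), "ddG pairs (",
      sprintf("%d%%", round(100 * x$level)), "bootstrap CIs )\n")
  for (nm in c("mue", "mse", "rmsd", "pearson", "spearman", "kendall_tau",
               "slope", "intercept")) {
    cat(sprintf("  %-12s %s\n", nm, format_ci(x[[nm]]$value, x[[nm]]$ci)))
  }
  invisible(x)
}
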