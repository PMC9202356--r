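#!/usr/bin/env Rscript
# Step 6: the full pipeline and the comparison statistics.
# Runs the end-to-end pipeline on the shipped example configuration (three
# Gaussian-chain transformations, both legs, TI + MBAR), producing the
# ddG table, overlap verdicts, TI-vs-FEP significance records, and the
# Table-style comparison report against the closed-form references; then
# examines the shape of a 48-replica free-energy distribution.

library(alchemr)
out <- "results/analysis"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

cfg <- read_run_config(system.file("extdata", "example-config.yaml",
                                   package = "alchemr"))
cfg$n_boot <- 2000
bundle <- run_pipeline(cfg, file.path(out, "pipeline"))
cat("Pipeline digest:", bundle$digest, "\n")
for (nm in names(bundle$transformations)) {
  tr <- bundle$transformations[[nm]]
  sg <- tr$significance
  cat(sprintf("%s: TI ddG %.3f+/-%.3f, MBAR ddG %.3f+/-%.3f, analytic %.3f; TI-FEP %ssignificant.\n",
              nm, tr$cycles$TI$ddg, tr$cycles$TI$sem, tr$cycles$MBAR$ddg,
              tr$cycles$MBAR$sem, tr$analytic_ddg,
              if (sg$significant) "" else "not "))
}
cat("\nTI comparison vs reference:\n")
print(bundle$comparison$TI)

## distribution shape of per-replica free energies at ensemble size 48
sys <- gaussian_chain_system(13, kf = c(1, 4), mu = c(0, 1))
big <- sample_gaussian_chain(generator_spec(sys, 250, 48, seed = 601))
ti48 <- ties_estimate(big, seed = 5)
dr <- distribution_stats(ti48$replica_values, seed = 6)
print(dr)
write.table(data.frame(replica = 1:48, delta_g = ti48$replica_values),
            file.path(out, "replica_dg_n48.tsv"),
            sep = "\t", row.names = FALSE, quote = FALSE)
flagged <- any(dr$normality_flag)
cat(sprintf("Gaussian-chain replicas look %s at the 90%% level (as expected for exact sampling).\n",
            if (flagged) "non-Gaussian" else "Gaussian"))
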