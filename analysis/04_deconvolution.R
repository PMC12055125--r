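#!/usr/bin/env Rscript
# Estimate the six placental cell-type proportions per sample by
# constrained projection (nonnegative weights summing to at most one)
# against the reference panel, and compare with the generator's truth.

library(gestwin)

beta <- as.matrix(read.table("results/qc/beta_qc.tsv", sep = "\t",
                             check.names = FALSE))
panel <- as.matrix(read.table("results/cohort/reference_panel.tsv",
                              sep = "\t", check.names = FALSE))

props <- estimate_proportions(beta, panel, renormalize = TRUE)
dir.create("results/deconv", showWarnings = FALSE, recursive = TRUE)
write.csv(props, "results/deconv/proportions.csv", row.names = FALSE)

cat("estimated cell-type proportions (%), cohort mean (sd):\n")
for (ct in colnames(panel))
  cat(sprintf("  %-20s %5.1f (%.1f)\n", ct, 100 * mean(props[[ct]]),
              100 * sd(props[[ct]])))
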