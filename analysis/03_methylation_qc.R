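#!/usr/bin/env Rscript
# Methylation QC in the fixed order: probe filters (detection p > 0.01 in
# > 10% of samples; cross-reactive list), sample filters (> 10% failing
# probes, median log2 intensity < 11, missing or discordant sex), twin
# deduplication, empirical Bayes batch adjustment with sex protected,
# gold-standard quantile normalization, PC outlier flag.

library(gestwin)
seed <- if (length(commandArgs(TRUE))) as.integer(commandArgs(TRUE)[1]) else 1L

cdir <- "results/cohort"
beta <- as.matrix(read.table(file.path(cdir, "beta.tsv"), sep = "\t",
                             check.names = FALSE))
detp <- as.matrix(read.table(file.path(cdir, "detection_p.tsv"), sep = "\t",
                             check.names = FALSE))
intensity <- read.csv(file.path(cdir, "intensity.csv"))
sheet <- read.csv(file.path(cdir, "samplesheet.csv"))

qc <- run_methqc(beta, detp, intensity, sheet,
                 x_probe_ids = grep("^cg_sexchr_", rownames(beta),
                                    value = TRUE),
                 seed = seed)

out <- "results/qc"
dir.create(out, recursive = TRUE, showWarnings = FALSE)
write.table(qc$beta, file.path(out, "beta_qc.tsv"), sep = "\t",
            quote = FALSE)
writeLines(jsonlite::toJSON(qc$report, auto_unbox = TRUE, pretty = TRUE,
                            digits = NA),
           file.path(out, "qc_report.json"))

cat(sprintf("probes: %d retained, %d dropped\n",
            qc$report$n_probes_retained, nrow(qc$report$dropped_probes)))
cat("samples dropped by reason:\n")
print(table(qc$report$dropped_samples$reason))
cat(sprintf("samples retained: %d\n", qc$report$n_samples_retained))
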