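#!/usr/bin/env Rscript
# Train an elastic-net gestational age clock on an independent synthetic
# training cohort sharing the analysis cohort's CpG biology, predict
# epigenetic GA on the QC'd analysis samples, and compute intrinsic
# (cell-adjusted) and extrinsic age-acceleration residuals.

library(gestwin)
seed <- if (length(commandArgs(TRUE))) as.integer(commandArgs(TRUE)[1]) else 1L

beta <- as.matrix(read.table("results/qc/beta_qc.tsv", sep = "\t",
                             check.names = FALSE))
participants <- read.csv("results/cohort/participants.csv")
props <- read.csv("results/deconv/proportions.csv", check.names = FALSE)

tr_cfg <- simulation_config(n_participants = 300, n_twin_pairs = 0,
                            n_low_intensity = 0, n_sex_discordant = 0,
                            seed = seed + 77L, biology_seed = seed)
tr <- simulate_cohort(tr_cfg)
rows <- grep("^cg_(clock|bg)_", rownames(tr$beta), value = TRUE)
clock <- train_clock(tr$beta[rows, ], tr$participants$ga_weeks, seed = seed)
cat(sprintf("clock: %d CpGs with nonzero weight, intercept %.2f weeks\n",
            length(clock$cpgs), clock$intercept))

ega <- predict_ega(beta, clock)
cga <- setNames(participants$ga_weeks, participants$participant_id)[names(ega)]
pm <- as.matrix(props[, setdiff(colnames(props), c("sample_id", "sum"))])
rownames(pm) <- props$sample_id
aa <- compute_age_accel(ega, cga, pm[names(ega), ])

dir.create("results/clock", showWarnings = FALSE, recursive = TRUE)
write.csv(data.frame(cpg = c("__intercept__", clock$cpgs),
                     weight = c(clock$intercept, unname(clock$weights))),
          "results/clock/clock_coefs.csv", row.names = FALSE)
write.csv(aa, "results/clock/ga_results.csv", row.names = FALSE)

cat(sprintf("epigenetic GA: mean %.1f (sd %.1f) weeks; chronologic %.1f (%.1f)\n",
            mean(aa$ega_weeks), sd(aa$ega_weeks),
            mean(aa$cga_weeks), sd(aa$cga_weeks)))
cat(sprintf("cor(epigenetic, chronologic GA) = %.2f\n",
            cor(aa$ega_weeks, aa$cga_weeks)))
cat(sprintf("%d samples with GA acceleration, %d with deceleration (intrinsic)\n",
            sum(aa$intrinsic_gaa > 0), sum(aa$intrinsic_gaa <= 0)))
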