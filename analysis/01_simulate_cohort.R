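#!/usr/bin/env Rscript
# Simulate the study cohort: monitoring stations with weekly pollutant
# series, pregnancies with residences and covariates, the methylation data
# bundle, and the ground-truth record. Writes plain-text tables under
# results/cohort/.

library(gestwin)
seed <- if (length(commandArgs(TRUE))) as.integer(commandArgs(TRUE)[1]) else 1L

cfg <- simulation_config(seed = seed)
co <- simulate_cohort(cfg)
out <- "results/cohort"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

write.csv(co$stations, file.path(out, "stations.csv"), row.names = FALSE)
write.csv(co$station_weekly, file.path(out, "station_weekly.csv"),
          row.names = FALSE)
write.csv(co$participants, file.path(out, "participants.csv"),
          row.names = FALSE)
write.table(co$beta, file.path(out, "beta.tsv"), sep = "\t", quote = FALSE)
write.table(co$detection_p, file.path(out, "detection_p.tsv"), sep = "\t",
            quote = FALSE)
write.csv(co$intensity, file.path(out, "intensity.csv"), row.names = FALSE)
write.csv(co$samplesheet, file.path(out, "samplesheet.csv"),
          row.names = FALSE)
write.table(co$panel, file.path(out, "reference_panel.tsv"), sep = "\t",
            quote = FALSE)
write.csv(data.frame(participant_id = names(co$truth$bio_ga),
                     bio_ga = co$truth$bio_ga,
                     cga = co$truth$cga,
                     windowed_mean_exposure =
                       co$truth$windowed_mean_exposure),
          file.path(out, "truth_ga.csv"), row.names = FALSE)

cat(sprintf("cohort: %d pregnancies (of them %d twin additions), %d stations\n",
            nrow(co$participants), cfg$n_twin_pairs, nrow(co$stations)))
cat(sprintf("chronologic GA: mean %.1f, sd %.1f weeks; %.0f%% preterm\n",
            mean(co$participants$ga_weeks), sd(co$participants$ga_weeks),
            100 * mean(co$participants$ga_weeks < 37)))
cat(sprintf("beta matrix: %d CpGs x %d samples; planted effect: %s weeks %d-%d, gamma %.1f\n",
            nrow(co$beta), ncol(co$beta), cfg$effect$pollutant,
            cfg$effect$window_start, cfg$effect$window_end,
            cfg$effect$gamma))
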