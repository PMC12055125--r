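#!/usr/bin/env Rscript
# Weekly distributed lag models on the unified 48-week axis (13
# preconception weeks + pregnancy weeks 1-35): polynomial lag bases with
# AIC degree selection, pointwise 95% intervals per 10-unit increment, and
# critical-window extraction.

library(gestwin)

aa <- read.csv("results/clock/ga_results.csv")
expo <- read.csv("results/exposure/weekly_exposures.csv")
participants <- read.csv("results/cohort/participants.csv")

dir.create("results/dlm", showWarnings = FALSE, recursive = TRUE)
for (pol in unique(expo$pollutant)) {
  sub <- expo[expo$pollutant == pol & expo$unified_week <= 48, ]
  X <- matrix(NA_real_, nrow(aa), 48,
              dimnames = list(aa$sample_id, NULL))
  idx <- cbind(match(sub$participant_id, aa$sample_id), sub$unified_week)
  keep <- !is.na(idx[, 1])
  X[idx[keep, , drop = FALSE]] <- sub$value[keep]
  cov <- participants[match(aa$sample_id, participants$participant_id), ]

  for (oc in c("intrinsic", "extrinsic")) {
    fit <- tryCatch(
      select_basis(aa[[paste0(oc, "_gaa")]], X, cov,
                   orders = c(1, 2, 3, 4)),
      error = function(e) NULL)
    if (is.null(fit)) {
      cat(sprintf("%s %s: model not estimable\n", pol, oc)); next
    }
    w <- extract_windows(fit)
    base <- sprintf("results/dlm/%s_%s", pol, oc)
    write.csv(fit$weekly_effects, paste0(base, "_weekly_effects.csv"),
              row.names = FALSE)
    write.csv(w, paste0(base, "_windows.csv"), row.names = FALSE)
    cat(sprintf("%s %s: degree %d selected (AIC %.1f), n = %d (%d dropped)\n",
                pol, oc, fit$basis$order, fit$aic, fit$n_used,
                fit$n_dropped))
    if (nrow(w) == 0) {
      cat("  no critical window (all pointwise CIs cover 0)\n")
    } else {
      for (i in seq_len(nrow(w)))
        cat(sprintf("  %s window %s to %s, peak %s\n", w$sign[i],
                    w$start_label[i], w$end_label[i], w$peak_label[i]))
    }
  }
}
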