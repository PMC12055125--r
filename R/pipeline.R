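# End-to-end pipeline: simulate -> interpolate exposures -> methylation QC
# -> cell deconvolution -> clock and age-acceleration residuals ->
# period-average association grid -> weekly distributed lag model. One
# master seed determines the whole run.

#' Run the full analysis pipeline on a synthetic cohort
#'
#' Simulates a cohort, assigns weekly exposures to residences by inverse
#' distance-squared interpolation, runs methylation QC (probe/sample
#' filters, twin dedup, empirical Bayes batch adjustment, gold-standard
#' normalization, PC outlier flag), estimates cell proportions by
#' constrained projection, trains an elastic-net gestational age clock on
#' an independently simulated training cohort (regressing chronologic GA on
#' beta values), computes intrinsic and extrinsic age-acceleration
#' residuals, fits the period-average association grid, and fits a weekly
#' distributed lag model for the effect pollutant with AIC basis selection.
#'
#' @param config a [simulation_config()].
#' @param n_training training-cohort size for the clock.
#' @param dlm_orders candidate polynomial degrees for the lag basis.
#' @return list with every intermediate product: `cohort`, `weekly_exposure`,
#'   `period_averages`, `qc`, `proportions`, `clock`, `age_accel`,
#'   `assoc_grid`, `dlm_fit`, `windows`.
#' @export
run_pipeline <- function(config = simulation_config(),
                         n_training = 300, dlm_orders = c(1, 2, 3, 4)) {
  cohort <- simulate_cohort(config)
  pollutants <- names(config$pollutants)

  weekly <- assign_weekly_exposures_all(cohort$participants,
                                        cohort$stations,
                                        cohort$station_weekly, pollutants)
  period_avg <- period_average_table(weekly, cohort$participants)

  qc <- run_methqc(cohort$beta, cohort$detection_p, cohort$intensity,
                   cohort$samplesheet,
                   x_probe_ids = grep("^cg_sexchr_", rownames(cohort$beta),
                                      value = TRUE),
                   seed = config$seed)
  kept <- colnames(qc$beta)

  props <- estimate_proportions(qc$beta, cohort$panel, renormalize = TRUE)
  prop_mat <- as.matrix(props[, colnames(cohort$panel)])
  rownames(prop_mat) <- props$sample_id

  # clock trained on an independent clean synthetic cohort against
  # chronologic GA, mirroring an externally trained clock
  tr_cfg <- config
  tr_cfg$n_participants <- as.integer(n_training)
  tr_cfg$n_twin_pairs <- 0L
  tr_cfg$n_low_intensity <- 0L
  tr_cfg$n_sex_discordant <- 0L
  tr_cfg$seed <- config$seed + 77L
  tr <- simulate_cohort(tr_cfg)
  tr_rows <- grep("^cg_(clock|bg)_", rownames(tr$beta), value = TRUE)
  clock <- train_clock(tr$beta[tr_rows, ], tr$participants$ga_weeks,
                       seed = config$seed)

  ega <- predict_ega(qc$beta, clock)
  cga <- stats::setNames(cohort$participants$ga_weeks,
                         cohort$participants$participant_id)[kept]
  accel <- compute_age_accel(ega, cga, prop_mat[kept, , drop = FALSE])

  cov_tab <- cohort$participants[, c("participant_id", "maternal_age",
                                     "race", "ethnicity", "education",
                                     "income", "bmi", "child_sex",
                                     "birth_season", "site")]
  assoc_grid <- run_analysis_grid(
    accel, period_avg, cov_tab,
    pollutants = pollutants,
    periods = c("preconception", "pregnancy", "trimester1", "trimester2",
                "trimester3"))

  # weekly DLM for the effect pollutant on the unified 48-week axis
  pol <- config$effect$pollutant
  wsub <- weekly[weekly$pollutant == pol & weekly$unified_week <= 48, ]
  Xw <- matrix(NA_real_, length(accel$sample_id), 48,
               dimnames = list(accel$sample_id, NULL))
  for (i in seq_along(accel$sample_id)) {
    s <- wsub[wsub$participant_id == accel$sample_id[i], ]
    Xw[i, s$unified_week] <- s$value
  }
  # weeks after birth are absent from the assigned series and stay NA, so
  # births before pregnancy week 35 drop out of the DLM as complete-case
  cov_kept <- cov_tab[match(accel$sample_id, cov_tab$participant_id), ]
  dlm_fit <- select_basis(accel$intrinsic_gaa, Xw, cov_kept,
                          kind = "polynomial", orders = dlm_orders)
  windows <- extract_windows(dlm_fit)

  list(cohort = cohort, weekly_exposure = weekly,
       period_averages = period_avg, qc = qc, proportions = props,
       clock = clock, age_accel = accel, assoc_grid = assoc_grid,
       dlm_fit = dlm_fit, windows = windows)
}
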