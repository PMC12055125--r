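# Period-average association models: individual analytic models (one
# exposure period at a time), mutually adjusted models (all periods of one
# pollutant simultaneously), and the full pollutant x period x outcome
# grid. Effects are reported per 10-unit increment with normal-theory
# (t-distribution) 95% confidence intervals and raw two-sided p-values; no
# multiple-testing adjustment is applied across the grid.

#' Fixed covariate dictionary
#'
#' Category levels and reference levels (first level) for the standard
#' covariate roster: maternal age at delivery (years, continuous), maternal
#' race, ethnicity, education, household income, prepregnancy BMI category,
#' child sex, birth season (warm Apr-Sep / cold Oct-Mar), study site.
#'
#' @return named list of factor level vectors.
#' @export
covariate_dictionary <- function() {
  list(
    race = c("White", "Asian", "Black", "Other"),
    ethnicity = c("NonHispanic", "Hispanic"),
    education = c("HSorSomeCollege", "Bachelors", "MastersPlus"),
    income = c("Under30k", "From30to50k", "From50to75k", "From75to100k",
               "Over100k"),
    bmi = c("UnderOrNormal", "Overweight", "Obese"),
    child_sex = c("male", "female"),
    birth_season = c("cold", "warm"),
    site = c("Philadelphia", "Baltimore", "Sacramento", "SanFrancisco")
  )
}

# Coerce the covariate table to the fixed dictionary (factors with fixed
# reference levels); unknown categories become NA and drop as incomplete.
gw_covariate_frame <- function(covariates) {
  dict <- covariate_dictionary()
  out <- data.frame(maternal_age = as.numeric(covariates$maternal_age))
  for (nm in names(dict)) {
    if (!nm %in% names(covariates))
      stop("covariate table missing column: ", nm)
    out[[nm]] <- factor(as.character(covariates[[nm]]), levels = dict[[nm]])
  }
  out
}

# Shared OLS engine: exposure columns first, then dummy-coded covariates.
gw_assoc_ols <- function(outcome, expo, covariates, scale_per,
                         conf_level) {
  cv <- gw_covariate_frame(covariates)
  dat <- cbind(data.frame(.y = outcome), expo, cv)
  dat <- dat[stats::complete.cases(dat), , drop = FALSE]
  n <- nrow(dat)
  fml <- stats::as.formula(paste(".y ~", paste(
    c(colnames(expo), "maternal_age", names(covariate_dictionary())),
    collapse = " + ")))
  mm_p <- ncol(stats::model.matrix(fml, utils::head(dat, min(n, 50L))))
  if (n <= mm_p + 5)
    stop("too few complete cases (", n, ") for ", mm_p, " parameters")
  fit <- stats::lm(fml, data = dat)
  sm <- summary(fit)$coefficients
  ci <- stats::confint(fit, level = conf_level)
  rows <- lapply(colnames(expo), function(term) {
    data.frame(
      term = term, n = n,
      beta_per_10 = sm[term, "Estimate"] * scale_per,
      ci_low = ci[term, 1] * scale_per,
      ci_high = ci[term, 2] * scale_per,
      p = sm[term, "Pr(>|t|)"],
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}

#' Individual analytic model for one exposure period
#'
#' Multivariable linear regression of an age-acceleration residual on one
#' period-average exposure, adjusting for the standard covariate roster,
#' restricted to complete cases. The slope is reported per
#' `scale_per` (10) concentration units.
#'
#' @param outcome residual vector (intrinsic or extrinsic GAA), weeks.
#' @param exposure period-average exposure vector, same order.
#' @param covariates covariate data frame (see [covariate_dictionary()]),
#'   same order.
#' @param scale_per report scale, concentration units (default 10).
#' @param conf_level confidence level (default 0.95).
#' @return one-row data frame: `n`, `beta_per_10`, `ci_low`, `ci_high`, `p`.
#' @export
fit_individual <- function(outcome, exposure, covariates, scale_per = 10,
                           conf_level = 0.95) {
  if (stats::var(exposure, na.rm = TRUE) < 1e-12)
    stop("constant exposure vector")
  expo <- data.frame(exposure = exposure)
  out <- gw_assoc_ols(outcome, expo, covariates, scale_per, conf_level)
  out$term <- NULL
  out
}

#' Mutually adjusted model across exposure periods
#'
#' One linear model with every period average of the same pollutant as a
#' simultaneous regressor plus the covariate roster; one estimate per
#' period. Periods correlated above 0.99 in the analysis sample are
#' rejected as non-identifiable.
#'
#' @param outcome residual vector, weeks.
#' @param exposures data frame or matrix, one column per period.
#' @inheritParams fit_individual
#' @return data frame with one row per period: `period`, `n`,
#'   `beta_per_10`, `ci_low`, `ci_high`, `p`.
#' @export
fit_mutually_adjusted <- function(outcome, exposures, covariates,
                                  scale_per = 10, conf_level = 0.95) {
  expo <- as.data.frame(exposures)
  if (ncol(expo) > 1) {
    cc <- stats::complete.cases(expo)
    cm <- stats::cor(expo[cc, , drop = FALSE])
    if (any(abs(cm[upper.tri(cm)]) > 0.99))
      stop("period averages correlated above 0.99: non-identifiable")
  }
  out <- gw_assoc_ols(outcome, expo, covariates, scale_per, conf_level)
  names(out)[names(out) == "term"] <- "period"
  out
}

#' Run the full association grid
#'
#' One estimate per pollutant x period x outcome cell, individual or
#' mutually adjusted models. Cells whose model fails (too few complete
#' cases, constant exposure) are recorded with the failure reason rather
#' than aborting the grid.
#'
#' @param age_accel data frame from [compute_age_accel()].
#' @param period_averages long table from [period_average_table()].
#' @param covariates covariate table with `participant_id`.
#' @param pollutants,periods,outcomes grid axes (`outcomes` among
#'   `"intrinsic"`, `"extrinsic"`).
#' @param model `"individual"` or `"mutual"`.
#' @param full_term restrict to chronologic GA >= 37 weeks before fitting.
#' @return data frame: `pollutant`, `period`, `outcome`, `model`, `n`,
#'   `beta_per_10`, `ci_low`, `ci_high`, `p`, `note`.
#' @export
run_analysis_grid <- function(age_accel, period_averages, covariates,
                              pollutants, periods,
                              outcomes = c("intrinsic", "extrinsic"),
                              model = c("individual", "mutual"),
                              full_term = FALSE) {
  model <- match.arg(model)
  if (full_term) {
    keep <- age_accel$sample_id[age_accel$cga_weeks >= 37]
    age_accel <- age_accel[age_accel$sample_id %in% keep, , drop = FALSE]
  }
  ids <- age_accel$sample_id
  cov <- covariates[match(ids, covariates$participant_id), , drop = FALSE]
  get_expo <- function(pol, per) {
    sub <- period_averages[period_averages$pollutant == pol &
                             period_averages$period == per, ]
    sub$value[match(ids, sub$participant_id)]
  }
  empty_row <- function(pol, per, oc, note) {
    data.frame(pollutant = pol, period = per, outcome = oc, model = model,
               n = NA_integer_, beta_per_10 = NA_real_, ci_low = NA_real_,
               ci_high = NA_real_, p = NA_real_, note = note,
               stringsAsFactors = FALSE)
  }
  rows <- list()
  for (pol in pollutants) {
    for (oc in outcomes) {
      y <- age_accel[[paste0(oc, "_gaa")]]
      if (model == "individual") {
        for (per in periods) {
          res <- tryCatch(
            fit_individual(y, get_expo(pol, per), cov),
            error = function(e) conditionMessage(e))
          rows[[length(rows) + 1L]] <- if (is.character(res)) {
            empty_row(pol, per, oc, res)
          } else {
            data.frame(pollutant = pol, period = per, outcome = oc,
                       model = model, res, note = "",
                       stringsAsFactors = FALSE)
          }
        }
      } else {
        expo <- as.data.frame(stats::setNames(
          lapply(periods, function(per) get_expo(pol, per)), periods))
        res <- tryCatch(
          fit_mutually_adjusted(y, expo, cov),
          error = function(e) conditionMessage(e))
        for (per in periods) {
          rows[[length(rows) + 1L]] <- if (is.character(res)) {
            empty_row(pol, per, oc, res)
          } else {
            r <- res[res$period == per, ]
            data.frame(pollutant = pol, period = per, outcome = oc,
                       model = model, n = r$n, beta_per_10 = r$beta_per_10,
                       ci_low = r$ci_low, ci_high = r$ci_high, p = r$p,
                       note = "", stringsAsFactors = FALSE)
          }
        }
      }
    }
  }
  do.call(rbind, rows)
}
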