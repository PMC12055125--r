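# Distributed lag models: basis construction and spanning, reductions to
# ordinary OLS, AIC basis selection, critical-window extraction, and
# full-term restriction.

test_that("polynomial lag bases have the expected structure and rank", {
  b0 <- build_lag_basis("polynomial", 0)
  expect_identical(ncol(b0$B), 1L)
  expect_true(all(b0$B == 1))
  b2 <- build_lag_basis("polynomial", 2)
  expect_identical(qr(b2$B)$rank, 3L)
  expect_error(build_lag_basis("polynomial", 7), "0..6")
  expect_error(build_lag_basis("natural_cubic_spline", 9), "2..8")
})

test_that("a df-4 spline basis spans natural cubics with the same knots", {
  bs <- build_lag_basis("natural_cubic_spline", 4)
  # oracle: a natural cubic interpolant through the basis knots
  knots <- c(1, as.vector(attr(splines::ns(1:48, df = 3,
                                           Boundary.knots = c(1, 48)),
                               "knots")), 48)
  set.seed(42)
  for (i in 1:5) {
    f <- splinefun(knots, rnorm(length(knots)), method = "natural")
    y <- f(1:48)
    resid <- stats::lm.fit(bs$B, y)$residuals
    expect_lt(max(abs(resid)), 1e-8)
  }
})

test_that("a degree-0 DLM reduces to cumulative-exposure regression", {
  d <- simulate_dlm_cohort(n = 100, gamma = -1.5, seed = 51)
  fit <- fit_dlm(d$outcome, d$weekly, d$covariates,
                 build_lag_basis("polynomial", 0))
  # oracle: same model with the 48-week sum as a single regressor
  cv <- d$covariates
  df <- cbind(data.frame(y = d$outcome, xsum = rowSums(d$weekly)), cv)
  ols <- stats::lm(y ~ xsum + maternal_age + race + ethnicity + education +
                     income + bmi + child_sex + birth_season + site,
                   data = df)
  s <- stats::coef(ols)[["xsum"]] * 10
  expect_equal(unname(fit$weekly_effects$estimate), rep(s, 48),
               tolerance = 1e-8)
  # theta reconstruction is definitional
  expect_identical(fit$weekly_effects$estimate,
                   as.vector(fit$basis$B %*% fit$eta) * 10)
})

test_that("an identity-basis DLM on orthonormal exposures equals per-week OLS", {
  set.seed(52)
  n <- 80
  raw <- matrix(rnorm(n * 48), n, 48)
  raw <- scale(raw, center = TRUE, scale = FALSE)
  X <- qr.Q(qr(raw))[, 1:48]              # orthonormal, centred columns
  theta_true <- c(rep(0, 20), rep(-0.5, 10), rep(0, 18))
  y <- as.vector(X %*% theta_true) + rnorm(n, 0, 0.1)
  idb <- structure(list(kind = "identity", order = 48L, n_lags = 48L,
                        B = diag(48)), class = "gw_lag_basis")
  fit <- fit_dlm(y, X, covariates = NULL, basis = idb, scale_per = 1)
  perweek <- sapply(1:48, function(j) stats::coef(stats::lm(y ~ X[, j]))[2])
  expect_equal(unname(fit$weekly_effects$estimate), unname(perweek),
               tolerance = 1e-8)
})

test_that("pointwise intervals are calibrated under the null", {
  set.seed(53)
  cov_rate <- replicate(150, {
    s <- sample.int(1e8, 1)
    d <- simulate_dlm_cohort(n = 150, gamma = 0, seed = s)
    f <- fit_dlm(d$outcome, d$weekly, d$covariates,
                 build_lag_basis("polynomial", 3))
    we <- f$weekly_effects
    mean(we$ci_low <= 0 & 0 <= we$ci_high)
  })
  expect_gte(mean(cov_rate), 0.92)
})

test_that("AIC selection prefers at least quadratic bases for a curved truth", {
  set.seed(54)
  picks <- replicate(60, {
    s <- sample.int(1e8, 1)
    d <- simulate_dlm_cohort(n = 150, gamma = -2, noise_sd = 0.5, seed = s)
    select_basis(d$outcome, d$weekly, d$covariates,
                 orders = c(1, 2, 3, 4))$basis$order
  })
  expect_gte(mean(picks >= 2), 0.9)
})

test_that("basis selection tie-breaking and degenerate candidate sets", {
  d <- simulate_dlm_cohort(n = 100, gamma = -1, seed = 55)
  dup <- select_basis(d$outcome, d$weekly, d$covariates, orders = c(3, 3))
  expect_identical(dup$basis$order, 3)
  expect_equal(dup$aic_table$aic[1], dup$aic_table$aic[2])
  single <- select_basis(d$outcome, d$weekly, d$covariates, orders = 2)
  expect_identical(single$basis$order, 2)
})

test_that("window extraction segments runs, labels weeks, and handles nulls", {
  fake_fit <- function(est, se) {
    structure(list(
      weekly_effects = data.frame(
        unified_week = 1:48,
        pregnancy_week = ifelse(1:48 > 13, 1:48 - 13L, NA_integer_),
        estimate = est, se = se,
        ci_low = est - 2 * se, ci_high = est + 2 * se),
      df_residual = 100), class = "gw_dlm_fit")
  }
  # all intervals cover zero: empty summary
  f0 <- fake_fit(rep(0, 48), rep(1, 48))
  expect_identical(nrow(extract_windows(f0)), 0L)

  # isolated significant weeks 5 and 7 give two runs of length 1
  est <- rep(0, 48); se <- rep(1, 48)
  est[c(5, 7)] <- 10; se[c(5, 7)] <- 0.1
  w <- extract_windows(fake_fit(est, se))
  expect_identical(nrow(w), 2L)
  expect_identical(w$start_week, w$end_week)
  expect_identical(w$start_week, c(5L, 7L))
  expect_identical(w$sign, c("positive", "positive"))
  expect_identical(w$start_label, c("preconception_week_5",
                                    "preconception_week_7"))

  # a pregnancy-week run is labelled on the pregnancy axis
  est2 <- rep(0, 48); se2 <- rep(1, 48)
  est2[34:44] <- -5; se2[34:44] <- 0.1
  w2 <- extract_windows(fake_fit(est2, se2))
  expect_identical(w2$start_label, "pregnancy_week_21")
  expect_identical(w2$end_label, "pregnancy_week_31")
  expect_identical(w2$sign, "negative")
  expect_true(w2$peak_week >= 34 && w2$peak_week <= 44)
})

test_that("detection power is nondecreasing in the planted effect size", {
  set.seed(56)
  rate <- sapply(c(-0.5, -2), function(g) {
    mean(replicate(40, {
      s <- sample.int(1e8, 1)
      d <- simulate_dlm_cohort(n = 150, gamma = g, seed = s)
      f <- fit_dlm(d$outcome, d$weekly, d$covariates,
                   build_lag_basis("polynomial", 3))
      w <- extract_windows(f)
      any(w$sign == "negative" & w$start_week <= 44 & w$end_week >= 34)
    }))
  })
  expect_lte(rate[1], rate[2])
})

test_that("participants with missing lag weeks are dropped and counted", {
  d <- simulate_dlm_cohort(n = 120, gamma = -1, seed = 57)
  X <- d$weekly
  X[3, 10] <- NA; X[7, 48] <- NA
  f <- fit_dlm(d$outcome, X, d$covariates, build_lag_basis("polynomial", 2))
  expect_identical(f$n_used, 118L)
  expect_identical(f$n_dropped, 2L)
})

test_that("full-term restriction keeps 37.0 weeks inclusively", {
  pp <- data.frame(participant_id = c("a", "b", "c"),
                   ga_weeks = c(37.0, 36.9, 40.1))
  out <- full_term_restrict(pp)
  expect_setequal(out$participant_id, c("a", "c"))
  expect_identical(attr(out, "n_dropped"), 1L)
  all_term <- data.frame(participant_id = "z", ga_weeks = 39)
  expect_identical(nrow(full_term_restrict(all_term)), 1L)
  expect_error(full_term_restrict(data.frame(ga_weeks = 30)), "remain")
})
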