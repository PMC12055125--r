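# Synthetic cohort generator: determinism, degenerate configurations, and
# agreement of the sampled data with the stated generative distributions.

test_that("constant field degenerates to the baseline and runs are bit-reproducible", {
  cfg <- simulation_config(
    n_participants = 5, n_stations = 3,
    pollutants = list(O3 = list(baseline = 26, amplitude = 0, noise_sd = 0,
                                gradient = 0)),
    effect = list(pollutant = "O3", window_start = 34, window_end = 44,
                  gamma = 0),
    seed = 4)
  st <- simulate_stations(cfg)
  expect_true(all(st$weekly$value == 26))

  cfg2 <- simulation_config(n_participants = 12, n_stations = 4, seed = 9)
  a <- simulate_cohort(cfg2)
  b <- simulate_cohort(cfg2)
  expect_identical(a$station_weekly, b$station_weekly)
  expect_identical(a$participants, b$participants)
  expect_identical(a$beta, b$beta)
  expect_identical(a$detection_p, b$detection_p)
})

test_that("noise-free station series has the closed-form sinusoid variance", {
  amp <- 7
  cfg <- simulation_config(
    n_participants = 1, n_stations = 1,
    pollutants = list(O3 = list(baseline = 100, amplitude = amp,
                                noise_sd = 0, gradient = 0)),
    effect = list(pollutant = "O3", window_start = 34, window_end = 44,
                  gamma = 0),
    seed = 2)
  st <- simulate_stations(cfg)
  v <- st$weekly$value[1:52]
  pop_var <- mean((v - mean(v))^2)   # variance of a sinusoid over one period
  expect_equal(pop_var, amp^2 / 2, tolerance = 1e-6)
})

test_that("empty region box is rejected", {
  expect_error(simulation_config(region = c(lon_min = -76, lon_max = -76,
                                            lat_min = 38, lat_max = 40)),
               "empty region")
})

test_that("participant generator honours the gestational age model", {
  cfg0 <- simulation_config(n_participants = 40, preterm_fraction = 0,
                            n_twin_pairs = 0, seed = 6)
  st <- simulate_stations(cfg0)
  pp <- simulate_participants(cfg0, st$field)
  expect_true(all(pp$participants$ga_weeks >= 37))

  cfg_empty <- simulation_config(n_participants = 0, n_twin_pairs = 0,
                                 seed = 6)
  pe <- simulate_participants(cfg_empty, st$field)
  expect_identical(nrow(pe$participants), 0L)

  # large-sample mean against the closed-form mixture truncated-normal mean
  f <- 0.08
  cfgN <- simulation_config(n_participants = 10000, preterm_fraction = f,
                            n_twin_pairs = 0, seed = 13)
  stN <- simulate_stations(simulation_config(n_participants = 1,
                                             n_stations = 2, seed = 13))
  ppN <- simulate_participants(cfgN, stN$field)
  expected <- f * oracle_tnorm_mean(39.2, 1.4, 28, 37) +
    (1 - f) * oracle_tnorm_mean(39.2, 1.4, 37, 42)
  expect_equal(mean(ppN$participants$ga_weeks), expected, tolerance = 0.05)
  expect_true(all(ppN$participants$ga_weeks >= 28 &
                    ppN$participants$ga_weeks <= 42))
})

test_that("noise-free linear-link clock CpGs are a deterministic function of GA", {
  cfg <- simulation_config(
    n_participants = 25, beta_noise_sd = 0, bio_noise_sd = 0,
    batch_layout = list(n_plates = 1, plate_shift = 0, plate_scale = 1),
    effect = list(pollutant = "O3", window_start = 34, window_end = 44,
                  gamma = 0),
    link = "linear", n_low_intensity = 0, n_sex_discordant = 0,
    n_twin_pairs = 0, detection_fail_rate = 0, seed = 8)
  co <- simulate_cohort(cfg)
  # bioGA == chronologic GA, so equal GA implies identical clock columns
  ga <- co$participants$ga_weeks
  dup <- which(duplicated(ga) | duplicated(ga, fromLast = TRUE))
  clock_rows <- grep("^cg_clock_", rownames(co$beta))
  if (length(dup) >= 2) {
    i <- dup[ga[dup] == ga[dup][1]][1:2]
    expect_equal(co$beta[clock_rows, i[1]], co$beta[clock_rows, i[2]])
  }
  m <- clock_model(co$truth$clock$intercept, co$truth$clock$weights)
  expect_true(co$truth$clock$exact)
  expect_equal(unname(predict_ega(co$beta, m)), unname(ga), tolerance = 1e-8)
})

test_that("beta values stay in [0,1] and cell proportions are a simplex", {
  co <- simulate_cohort(simulation_config(n_participants = 30, seed = 17))
  expect_true(all(co$beta >= 0 & co$beta <= 1))
  expect_true(all(co$detection_p >= 0 & co$detection_p <= 1))
  cp <- co$truth$cell_proportions
  expect_true(all(cp >= 0))
  expect_equal(unname(rowSums(cp)), rep(1, nrow(cp)), tolerance = 1e-12)
})

test_that("detection failures occur at the configured rate", {
  cfg <- simulation_config(n_participants = 100, n_clock_cpgs = 300,
                           n_background_cpgs = 700, n_twin_pairs = 0,
                           detection_fail_rate = 0.02, seed = 23)
  co <- simulate_cohort(cfg)
  expect_lt(abs(mean(co$detection_p > 0.01) - 0.02), 0.005)
})

test_that("an effect pollutant missing from the config is rejected", {
  cfg <- simulation_config(n_participants = 10, seed = 3)
  cfg$effect$pollutant <- "SO2"
  st <- simulate_stations(cfg)
  expect_error(simulate_participants(cfg, st$field), "SO2")
})

test_that("changing the cohort seed leaves shared biology untouched", {
  c1 <- simulation_config(n_participants = 20, seed = 31, biology_seed = 5)
  c2 <- simulation_config(n_participants = 20, seed = 32, biology_seed = 5)
  a <- simulate_cohort(c1); b <- simulate_cohort(c2)
  expect_identical(a$panel, b$panel)
  expect_equal(a$truth$clock$weights, b$truth$clock$weights)
  expect_false(identical(a$beta, b$beta))
})
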