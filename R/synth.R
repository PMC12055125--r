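# Synthetic cohort generator. Emulates the data structures of a
# station-monitored pregnancy cohort with placental methylation at birth:
# spatially structured seasonal weekly pollutant fields sampled at stations,
# pregnancy calendars, beta values whose clock CpGs drift with biological
# gestational age, cell-type mixing against a reference panel, plate batch
# effects, detection-p failures, and a planted exposure effect on biological
# gestational age confined to a configurable week window. Every run carries
# a ground-truth record so downstream stages can be tested against known
# answers.

#' Simulation configuration
#'
#' Defaults describe the emulated study conditions: a cohort of 103
#' pregnancies with chronologic gestational age 39.2 (SD 1.4) weeks, four
#' pollutants at the cohort's observed concentration levels, and a planted
#' negative ozone effect of -0.7 weeks of biological gestational age per
#' 10 ppb, confined to unified weeks 34-44 (pregnancy weeks 21-31).
#'
#' @param n_participants number of pregnancies.
#' @param n_stations number of monitoring stations.
#' @param region bounding box, named numeric
#'   `c(lon_min, lon_max, lat_min, lat_max)` in decimal degrees.
#' @param pollutants named list; each element a list with `baseline`
#'   (concentration units), `amplitude` (seasonal sine amplitude),
#'   `noise_sd` (marginal week-to-week noise SD), `gradient`
#'   (concentration change per degree along the SW-NE diagonal).
#' @param n_clock_cpgs,n_background_cpgs,n_sex_cpgs CpG counts by role.
#' @param beta_noise_sd measurement noise SD on the beta scale.
#' @param batch_layout list `n_plates`, `plate_shift` (logit-scale location
#'   shift between adjacent plates), `plate_scale` (multiplicative noise
#'   scale between adjacent plates).
#' @param effect list `pollutant`, `window_start`, `window_end` (unified
#'   weeks in 1-48), `gamma` (weeks of biological-GA shift per 10
#'   concentration units of windowed mean exposure).
#' @param detection_fail_rate i.i.d. probability a detection p-value exceeds
#'   0.01.
#' @param ga_mean,ga_sd chronologic gestational age distribution, weeks.
#' @param preterm_fraction probability mass below 37 weeks.
#' @param bio_noise_sd SD of the individual biological-GA noise, weeks.
#' @param n_weeks,series_start length and first week-start date of the
#'   station series (must cover every pregnancy calendar).
#' @param n_low_intensity,n_sex_discordant,n_twin_pairs planted
#'   QC-removable samples.
#' @param link generation link for clock CpGs: `"logit"` keeps beta in
#'   (0,1) by construction; `"linear"` makes beta an exact linear function
#'   of biological GA (clean clock fixtures).
#' @param seed master seed; component streams are derived by fixed offsets.
#' @param biology_seed seed for the feature-level biology (clock CpG
#'   intercepts and slopes, background CpG levels, the reference panel).
#'   Defaults to `seed`. Cohorts sharing a `biology_seed` but differing in
#'   `seed` are independent samples from the same biological universe —
#'   required when a clock trained on one cohort is applied to another.
#' @return validated config, class `gw_config`.
#' @export
simulation_config <- function(
    n_participants = 103,
    n_stations = 20,
    region = c(lon_min = -77.5, lon_max = -75.5,
               lat_min = 38.5, lat_max = 40.5),
    pollutants = list(
      NO2  = list(baseline = 13,   amplitude = 3, noise_sd = 2,   gradient = 1.5),
      O3   = list(baseline = 26,   amplitude = 7, noise_sd = 3,   gradient = 1.0),
      PM25 = list(baseline = 10,   amplitude = 2, noise_sd = 1.5, gradient = 0.8),
      PM10 = list(baseline = 17.5, amplitude = 3, noise_sd = 2.5, gradient = 1.2)
    ),
    n_clock_cpgs = 200, n_background_cpgs = 800, n_sex_cpgs = 20,
    beta_noise_sd = 0.02,
    batch_layout = list(n_plates = 2, plate_shift = 0.15, plate_scale = 1.05),
    effect = list(pollutant = "O3", window_start = 34, window_end = 44,
                  gamma = -0.7),
    detection_fail_rate = 0.005,
    ga_mean = 39.2, ga_sd = 1.4, preterm_fraction = 0.08,
    bio_noise_sd = 1.2,
    n_weeks = 112, series_start = as.Date("2009-09-28"),
    n_low_intensity = 2, n_sex_discordant = 2, n_twin_pairs = 2,
    link = c("logit", "linear"),
    seed = 1, biology_seed = NULL) {
  link <- match.arg(link)
  if (is.null(biology_seed)) biology_seed <- seed
  if (region["lon_max"] <= region["lon_min"] ||
      region["lat_max"] <= region["lat_min"])
    stop("empty region bounding box")
  if (n_stations < 1) stop("need at least one station")
  if (n_weeks < 60) stop("need at least 60 weeks of station series")
  ws <- effect$window_start; we <- effect$window_end
  if (ws < 1 || we > 48 || ws > we)
    stop("effect window weeks must lie within [1, 48]")
  for (f in c(preterm_fraction, detection_fail_rate, beta_noise_sd))
    if (f < 0 || f > 1) stop("fractions must lie in [0, 1]")
  cfg <- list(
    n_participants = as.integer(n_participants),
    n_stations = as.integer(n_stations), region = region,
    pollutants = pollutants, n_clock_cpgs = as.integer(n_clock_cpgs),
    n_background_cpgs = as.integer(n_background_cpgs),
    n_sex_cpgs = as.integer(n_sex_cpgs), beta_noise_sd = beta_noise_sd,
    batch_layout = batch_layout, effect = effect,
    detection_fail_rate = detection_fail_rate,
    ga_mean = ga_mean, ga_sd = ga_sd, preterm_fraction = preterm_fraction,
    bio_noise_sd = bio_noise_sd, n_weeks = as.integer(n_weeks),
    series_start = as.Date(series_start),
    n_low_intensity = as.integer(n_low_intensity),
    n_sex_discordant = as.integer(n_sex_discordant),
    n_twin_pairs = as.integer(n_twin_pairs), link = link,
    seed = as.integer(seed), biology_seed = as.integer(biology_seed)
  )
  class(cfg) <- "gw_config"
  cfg
}

# Stationary AR(1) series with marginal SD s.
gw_ar1 <- function(n, rho, s) {
  if (s == 0 || n == 0L) return(numeric(n))
  x <- numeric(n)
  x[1] <- stats::rnorm(1, 0, s)
  innov_sd <- s * sqrt(1 - rho^2)
  for (t in seq_len(n)[-1]) x[t] <- rho * x[t - 1] + stats::rnorm(1, 0, innov_sd)
  x
}

# Projection of a coordinate onto the SW-NE diagonal, in degrees from the
# region centre; carries the spatial gradient.
gw_proj <- function(lon, lat, region) {
  ((lon - mean(region[c("lon_min", "lon_max")])) +
     (lat - mean(region[c("lat_min", "lat_max")]))) / sqrt(2)
}

#' Simulate monitoring stations and their weekly pollutant series
#'
#' Each station-week value is
#' `baseline + gradient * projection + amplitude * sin(2*pi*week/52 + phase)
#'  + regional AR(1) + local noise`, floored at 0. The week-to-week noise is
#' split into a regional AR(1) component shared across space (70% of the
#' variance) and station-local white noise (30%), so nearby locations carry
#' information about each other.
#'
#' @param config a [simulation_config()].
#' @return list with `stations` (station table), `weekly` (long table:
#'   `station_id`, `pollutant`, `week_start_date`, `value`) and `field`
#'   (the latent generative field, used to evaluate ground-truth exposures
#'   at arbitrary coordinates).
#' @export
simulate_stations <- function(config) {
  set.seed(gw_stream_seed(config$seed, "stations"))
  r <- config$region
  stations <- data.frame(
    station_id = sprintf("st%02d", seq_len(config$n_stations)),
    longitude = stats::runif(config$n_stations, r["lon_min"], r["lon_max"]),
    latitude = stats::runif(config$n_stations, r["lat_min"], r["lat_max"]),
    stringsAsFactors = FALSE
  )
  week_starts <- config$series_start + 7L * (seq_len(config$n_weeks) - 1L)
  field <- list(region = r, week_starts = week_starts,
                pollutants = list())
  rows <- list()
  for (pol in names(config$pollutants)) {
    pp <- config$pollutants[[pol]]
    phase <- stats::runif(1, 0, 2 * pi)
    regional <- gw_ar1(config$n_weeks, rho = 0.6, s = pp$noise_sd * sqrt(0.7))
    local_sd <- pp$noise_sd * sqrt(0.3)
    seasonal <- pp$amplitude * sin(2 * pi * seq_len(config$n_weeks) / 52 + phase)
    field$pollutants[[pol]] <- list(baseline = pp$baseline,
                                    gradient = pp$gradient, phase = phase,
                                    seasonal = seasonal, regional = regional,
                                    local_sd = local_sd)
    for (i in seq_len(config$n_stations)) {
      base <- pp$baseline + pp$gradient *
        gw_proj(stations$longitude[i], stations$latitude[i], r)
      vals <- base + seasonal + regional +
        stats::rnorm(config$n_weeks, 0, local_sd)
      rows[[length(rows) + 1L]] <- data.frame(
        station_id = stations$station_id[i], pollutant = pol,
        week_start_date = week_starts, value = pmax(vals, 0),
        stringsAsFactors = FALSE
      )
    }
  }
  list(stations = stations, weekly = do.call(rbind, rows), field = field)
}

# Ground-truth exposure at a residence: the same generative field evaluated
# at the residence coordinates (deterministic + regional parts shared with
# the stations, plus a fresh local-noise realization), so the
# exposure-assignment error of interpolation is realistically nonzero.
gw_field_at <- function(field, lon, lat, pollutant, week_bins) {
  fp <- field$pollutants[[pollutant]]
  ok <- week_bins >= 1 & week_bins <= length(fp$seasonal)
  out <- rep(NA_real_, length(week_bins))
  base <- fp$baseline + fp$gradient * gw_proj(lon, lat, field$region)
  out[ok] <- base + fp$seasonal[week_bins[ok]] + fp$regional[week_bins[ok]] +
    stats::rnorm(sum(ok), 0, fp$local_sd)
  pmax(out, 0)
}

# Fixed covariate sampling probabilities (cohort-frequency dictionaries);
# recorded in the truth record.
gw_covariate_probs <- function() {
  list(
    race = c(White = 0.64, Asian = 0.15, Black = 0.11, Other = 0.10),
    ethnicity = c(NonHispanic = 0.82, Hispanic = 0.18),
    education = c(HSorSomeCollege = 0.42, Bachelors = 0.27,
                  MastersPlus = 0.31),
    income = c(Under30k = 0.11, From30to50k = 0.18, From50to75k = 0.17,
               From75to100k = 0.20, Over100k = 0.34),
    bmi = c(UnderOrNormal = 0.41, Overweight = 0.31, Obese = 0.28),
    child_sex = c(male = 0.56, female = 0.44),
    site = c(Philadelphia = 0.27, Baltimore = 0.25, Sacramento = 0.29,
             SanFrancisco = 0.19)
  )
}

gw_draw_covariates <- function(n) {
  pr <- gw_covariate_probs()
  draw <- function(p) factor(sample(names(p), n, replace = TRUE, prob = p),
                             levels = names(p))
  data.frame(
    maternal_age = round(gw_rtnorm(n, 34.1, 4.3, 18, 50), 1),
    race = draw(pr$race), ethnicity = draw(pr$ethnicity),
    education = draw(pr$education), income = draw(pr$income),
    bmi = draw(pr$bmi), child_sex = draw(pr$child_sex), site = draw(pr$site),
    stringsAsFactors = FALSE
  )
}

# Mixture truncated-normal GA at birth: preterm_fraction of the mass on
# [28, 37), the rest on [37, 42].
gw_draw_ga <- function(n, ga_mean, ga_sd, preterm_fraction) {
  preterm <- stats::runif(n) < preterm_fraction
  ga <- numeric(n)
  ga[preterm] <- gw_rtnorm(sum(preterm), ga_mean, ga_sd, 28, 37 - 1e-9)
  ga[!preterm] <- gw_rtnorm(sum(!preterm), ga_mean, ga_sd, 37, 42)
  ga
}

#' Simulate participants, pregnancy calendars, and ground-truth exposures
#'
#' Residences are uniform in the region box; conception dates uniform over
#' one calendar year (so birth seasons are balanced); gestational age at
#' birth follows a truncated normal on \[28, 42\] weeks with
#' `preterm_fraction` of the mass below 37. Biological gestational age is
#' chronologic GA plus `gamma * (mean windowed true exposure) / 10` plus
#' individual noise.
#'
#' @param config a [simulation_config()].
#' @param field latent field from [simulate_stations()].
#' @return list with `participants` (table) and `truth` (ground-truth
#'   record: true weekly exposures, biological GA, cell proportions,
#'   covariate dictionaries, planted effect).
#' @export
simulate_participants <- function(config, field) {
  if (!config$effect$pollutant %in% names(config$pollutants))
    stop("effect pollutant not in config: ", config$effect$pollutant)
  set.seed(gw_stream_seed(config$seed, "participants"))
  n0 <- config$n_participants
  if (n0 == 0L) {
    empty <- data.frame(participant_id = character(0), family_id = character(0),
                        longitude = numeric(0), latitude = numeric(0),
                        conception_date = as.Date(character(0)),
                        ga_weeks = numeric(0))
    return(list(participants = empty,
                truth = list(weekly_exposure = NULL, bio_ga = numeric(0))))
  }
  r <- config$region
  df <- data.frame(
    participant_id = sprintf("p%03d", seq_len(n0)),
    longitude = stats::runif(n0, r["lon_min"], r["lon_max"]),
    latitude = stats::runif(n0, r["lat_min"], r["lat_max"]),
    conception_date = config$series_start + 91L +
      sample(0:363, n0, replace = TRUE),
    ga_weeks = round(gw_draw_ga(n0, config$ga_mean, config$ga_sd,
                                config$preterm_fraction), 1),
    stringsAsFactors = FALSE
  )
  df$family_id <- df$participant_id
  df <- cbind(df, gw_draw_covariates(n0))

  # twin pregnancies duplicate the pregnancy-level record under a new id
  if (config$n_twin_pairs > 0L) {
    src <- sample(n0, config$n_twin_pairs)
    twins <- df[src, , drop = FALSE]
    twins$participant_id <- sprintf("p%03dt", src)
    df <- rbind(df, twins)
    rownames(df) <- NULL
  }
  n <- nrow(df)
  birth <- df$conception_date + round(df$ga_weeks * 7)
  m <- as.integer(format(birth, "%m"))
  df$birth_season <- factor(ifelse(m >= 4 & m <= 9, "warm", "cold"),
                            levels = c("cold", "warm"))

  # ground-truth weekly exposures at the residence
  exp_rows <- vector("list", n * length(config$pollutants))
  k <- 1L
  win_mean <- numeric(n)
  ws <- config$effect$window_start; we <- config$effect$window_end
  for (i in seq_len(n)) {
    weeks <- unified_week_axis(df$ga_weeks[i])
    starts <- unified_week_start(df$conception_date[i], weeks)
    bins <- as.integer(starts + 3L - config$series_start) %/% 7L + 1L
    for (pol in names(config$pollutants)) {
      vals <- gw_field_at(field, df$longitude[i], df$latitude[i], pol, bins)
      exp_rows[[k]] <- data.frame(participant_id = df$participant_id[i],
                                  pollutant = pol, unified_week = weeks,
                                  value = vals, stringsAsFactors = FALSE)
      if (pol == config$effect$pollutant) {
        in_win <- weeks >= ws & weeks <= we
        win_mean[i] <- mean(vals[in_win])
      }
      k <- k + 1L
    }
  }
  bio_ga <- df$ga_weeks + config$effect$gamma * win_mean / 10 +
    stats::rnorm(n, 0, config$bio_noise_sd)

  # true placental cell proportions: Dirichlet around the cohort-mean
  # composition, concentration tuned to the observed spread
  cell_mean <- c(syncytiotrophoblast = 0.645, trophoblasts = 0.133,
                 hofbauer = 0.028, endothelial = 0.074, stromal = 0.110,
                 nrbc = 0.043)
  alpha <- cell_mean * 63
  g <- matrix(stats::rgamma(n * 6, shape = rep(alpha, each = n)), nrow = n)
  props <- g / rowSums(g)
  colnames(props) <- names(cell_mean)
  rownames(props) <- df$participant_id

  truth <- list(
    weekly_exposure = do.call(rbind, exp_rows),
    bio_ga = stats::setNames(bio_ga, df$participant_id),
    cga = stats::setNames(df$ga_weeks, df$participant_id),
    windowed_mean_exposure = stats::setNames(win_mean, df$participant_id),
    cell_proportions = props,
    gamma = config$effect$gamma,
    window = c(start = ws, end = we),
    effect_pollutant = config$effect$pollutant,
    covariate_probs = gw_covariate_probs()
  )
  list(participants = df, truth = truth)
}

#' Simulate a placental cell-type reference panel
#'
#' 600 CpGs by 6 placental cell types (syncytiotrophoblast, trophoblasts,
#' Hofbauer, endothelial, stromal, nucleated red blood cells); entries drawn
#' from a bimodal beta distribution so columns are well separated (pairwise
#' correlations far below 0.7). Synthetic: stands in for a sorted-cell
#' reference which is external to this pipeline.
#'
#' @param config a [simulation_config()].
#' @param n_cpgs panel size.
#' @return numeric matrix, CpGs by cell types.
#' @export
simulate_reference_panel <- function(config, n_cpgs = 600) {
  set.seed(gw_stream_seed(config$biology_seed, "panel"))
  types <- c("syncytiotrophoblast", "trophoblasts", "hofbauer",
             "endothelial", "stromal", "nrbc")
  panel <- matrix(stats::rbeta(n_cpgs * length(types), 0.45, 0.45),
                  nrow = n_cpgs, ncol = length(types),
                  dimnames = list(sprintf("cg_panel_%03d", seq_len(n_cpgs)),
                                  types))
  pmin(pmax(panel, 0.02), 0.98)
}

#' Simulate the methylation data bundle
#'
#' Clock CpGs drift with biological gestational age (logit-linear by
#' default, or exactly linear on the beta scale with `link = "linear"`);
#' background CpGs carry no GA signal; panel CpGs are cell-proportion
#' weighted mixtures of the reference columns; sex-chromosome CpGs separate
#' males (low) from females (intermediate, X-inactivation). Plate batch
#' effects act on the logit scale with per-feature heterogeneity. Detection
#' p-values fail i.i.d. at `detection_fail_rate`; the intensity sheet plants
#' `n_low_intensity` low-intensity samples; the samplesheet plants
#' `n_sex_discordant` sex-discordant reports.
#'
#' @param config a [simulation_config()].
#' @param participants participant table from [simulate_participants()].
#' @param truth truth record from [simulate_participants()].
#' @param panel reference panel from [simulate_reference_panel()].
#' @return list: `beta`, `detection_p` (CpG x sample matrices), `intensity`,
#'   `samplesheet` (data frames), and `truth_clock` (the generative clock:
#'   exact for `link = "linear"`, the linearization at the GA centre for
#'   `link = "logit"`).
#' @export
simulate_methylation <- function(config, participants, truth, panel) {
  if (!config$effect$pollutant %in% names(config$pollutants))
    stop("effect pollutant not in config: ", config$effect$pollutant)
  n <- nrow(participants)
  ids <- participants$participant_id
  bio <- truth$bio_ga[ids]
  ga_c <- config$ga_mean
  n_clock <- config$n_clock_cpgs
  n_bg <- config$n_background_cpgs

  # feature-level biology: shared across cohorts with the same biology_seed
  set.seed(gw_stream_seed(config$biology_seed, "methylation"))
  a_clock <- stats::runif(n_clock,
                          if (config$link == "logit") -1 else 0.3,
                          if (config$link == "logit") 1 else 0.7)
  b_mag <- stats::runif(n_clock,
                        if (config$link == "logit") 0.05 else 0.005,
                        if (config$link == "logit") 0.12 else 0.015)
  b_clock <- b_mag * sample(c(-1, 1), n_clock, replace = TRUE)
  a_bg <- stats::runif(n_bg, -2, 2)

  # sample-level realization: noise, batches, detection failures
  set.seed(gw_stream_seed(config$seed, "methylation") + 7L)
  nP <- config$batch_layout$n_plates
  plate <- sample(rep_len(seq_len(nP), n))
  plate_mu <- config$batch_layout$plate_shift * (seq_len(nP) - (nP + 1) / 2)
  plate_scale <- config$batch_layout$plate_scale ^
    (seq_len(nP) - (nP + 1) / 2)
  tau <- abs(config$batch_layout$plate_shift) / 2

  n_sex <- config$n_sex_cpgs
  sd_logit <- 4 * config$beta_noise_sd

  blocks <- list()

  # per-feature, per-plate batch location effects (empirical Bayes style
  # heterogeneity around the plate mean)
  batch_gamma <- function(n_feat) {
    g <- matrix(stats::rnorm(n_feat * nP, rep(plate_mu, each = n_feat), tau),
                nrow = n_feat)
    if (tau == 0) g <- matrix(rep(plate_mu, each = n_feat), nrow = n_feat)
    g
  }

  # clock CpGs
  g_clock <- batch_gamma(n_clock)
  if (config$link == "logit") {
    eta <- outer(a_clock, rep(1, n)) + outer(b_clock, bio - ga_c) +
      g_clock[, plate] +
      matrix(stats::rnorm(n_clock * n, 0, sd_logit), n_clock) *
        rep(plate_scale[plate], each = n_clock)
    beta_clock <- gw_expit(eta)
    # linearization of the generative map at the GA centre: approximate
    p0 <- gw_expit(a_clock)
    slope <- b_clock * p0 * (1 - p0)
    truth_clock <- list(
      cpgs = sprintf("cg_clock_%03d", seq_len(n_clock)),
      weights = 1 / (n_clock * slope),
      intercept = ga_c - sum(p0 / (n_clock * slope)),
      exact = FALSE
    )
  } else {
    beta_clock <- outer(a_clock, rep(1, n)) + outer(b_clock, bio - ga_c) +
      0.25 * g_clock[, plate] +
      matrix(stats::rnorm(n_clock * n, 0, config$beta_noise_sd), n_clock) *
        rep(plate_scale[plate], each = n_clock)
    beta_clock <- pmin(pmax(beta_clock, 0), 1)
    truth_clock <- list(
      cpgs = sprintf("cg_clock_%03d", seq_len(n_clock)),
      weights = 1 / (n_clock * b_clock),
      intercept = ga_c - sum(a_clock / (n_clock * b_clock)),
      exact = TRUE
    )
  }
  rownames(beta_clock) <- truth_clock$cpgs
  names(truth_clock$weights) <- truth_clock$cpgs
  blocks$clock <- beta_clock

  # background CpGs: no GA dependence
  g_bg <- batch_gamma(n_bg)
  eta_bg <- outer(a_bg, rep(1, n)) + g_bg[, plate] +
    matrix(stats::rnorm(n_bg * n, 0, sd_logit), n_bg) *
      rep(plate_scale[plate], each = n_bg)
  beta_bg <- gw_expit(eta_bg)
  rownames(beta_bg) <- sprintf("cg_bg_%04d", seq_len(n_bg))
  blocks$bg <- beta_bg

  # panel CpGs: cell-proportion weighted mixture of reference columns,
  # batch effect applied on the logit scale
  props <- truth$cell_proportions[ids, , drop = FALSE]
  mix <- panel %*% t(props)
  g_panel <- batch_gamma(nrow(panel))
  eta_panel <- gw_logit(mix) + g_panel[, plate] +
    matrix(stats::rnorm(nrow(panel) * n, 0, sd_logit), nrow(panel))
  beta_panel <- gw_expit(eta_panel)
  rownames(beta_panel) <- rownames(panel)
  blocks$panel <- beta_panel

  # sex-chromosome CpGs: females intermediate, males low
  female <- participants$child_sex == "female"
  mu_sex <- ifelse(female, -0.2, -1.7)
  eta_sex <- outer(rep(0, n_sex), mu_sex, function(a, b) b) +
    matrix(stats::rnorm(n_sex * n, 0, 0.3), n_sex)
  beta_sex <- gw_expit(eta_sex)
  rownames(beta_sex) <- sprintf("cg_sexchr_%02d", seq_len(n_sex))
  blocks$sex <- beta_sex

  beta <- do.call(rbind, blocks)
  rownames(beta) <- unlist(lapply(blocks, rownames), use.names = FALSE)
  colnames(beta) <- ids

  # detection p-values: failures (p > 0.01) i.i.d. at the configured rate
  fail <- matrix(stats::runif(length(beta)) < config$detection_fail_rate,
                 nrow = nrow(beta))
  detp <- matrix(stats::runif(length(beta), 0, 0.01), nrow = nrow(beta),
                 dimnames = dimnames(beta))
  detp[fail] <- stats::runif(sum(fail), 0.01 + 1e-12, 1)

  intensity <- data.frame(sample_id = ids,
                          median_log2_intensity =
                            stats::rnorm(n, 12.5, 0.4),
                          stringsAsFactors = FALSE)
  low_ids <- character(0)
  if (config$n_low_intensity > 0L) {
    low_ids <- sample(ids, min(config$n_low_intensity, n))
    intensity$median_log2_intensity[match(low_ids, ids)] <-
      stats::runif(length(low_ids), 10, 10.9)
  }

  reported_sex <- as.character(participants$child_sex)
  disc_ids <- character(0)
  if (config$n_sex_discordant > 0L) {
    disc_ids <- sample(setdiff(ids, low_ids),
                       min(config$n_sex_discordant, n))
    j <- match(disc_ids, ids)
    reported_sex[j] <- ifelse(reported_sex[j] == "male", "female", "male")
  }

  samplesheet <- data.frame(
    sample_id = ids, participant_id = ids,
    family_id = participants$family_id,
    reported_sex = reported_sex, plate = plate,
    position = (seq_len(n) - 1L) %% 12L + 1L,
    stringsAsFactors = FALSE
  )

  list(beta = beta, detection_p = detp, intensity = intensity,
       samplesheet = samplesheet, truth_clock = truth_clock,
       planted = list(low_intensity = low_ids, sex_discordant = disc_ids))
}

#' Simulate a complete cohort
#'
#' Orchestrates [simulate_stations()], [simulate_participants()],
#' [simulate_reference_panel()] and [simulate_methylation()] under one
#' master seed; identical config and seed give bit-identical output.
#'
#' @param config a [simulation_config()].
#' @return list of class `gw_cohort` with every simulated table plus the
#'   `truth` record.
#' @export
simulate_cohort <- function(config = simulation_config()) {
  st <- simulate_stations(config)
  pp <- simulate_participants(config, st$field)
  panel <- simulate_reference_panel(config)
  meth <- simulate_methylation(config, pp$participants, pp$truth, panel)
  truth <- pp$truth
  truth$clock <- meth$truth_clock
  truth$planted_qc <- meth$planted
  structure(list(
    stations = st$stations, station_weekly = st$weekly, field = st$field,
    participants = pp$participants, panel = panel,
    beta = meth$beta, detection_p = meth$detection_p,
    intensity = meth$intensity, samplesheet = meth$samplesheet,
    truth = truth, config = config
  ), class = "gw_cohort")
}

#' Reduced-form cohort for association-model calibration
#'
#' Draws period-average exposures, the standard covariate set, and an
#' age-acceleration outcome directly from the generative model
#' `outcome = gamma * exposure_effect_period / 10 + covariate effects +
#' noise`, skipping the methylation layer. Used for type-I error,
#' parameter-recovery and mutual-adjustment calibration studies where
#' thousands of cohorts are fitted.
#'
#' @param n participants per cohort.
#' @param gamma planted effect, weeks per 10 concentration units (0 = null).
#' @param effect_period period carrying the effect.
#' @param exposure_mean,exposure_sd marginal distribution of the period
#'   averages (defaults: pregnancy-average ozone levels, ppb).
#' @param periods named periods to draw.
#' @param period_cor correlation between consecutive period averages.
#' @param noise_sd residual SD of the outcome, weeks.
#' @param seed RNG seed.
#' @return list: `data` (outcome, one exposure column per period,
#'   covariates), `truth` (planted gamma and period).
#' @export
simulate_association_cohort <- function(n = 100, gamma = -0.7,
                                        effect_period = "pregnancy",
                                        exposure_mean = 25.8,
                                        exposure_sd = 3.9,
                                        periods = c("preconception",
                                                    "pregnancy"),
                                        period_cor = 0, noise_sd = 1,
                                        seed = 1) {
  set.seed(gw_stream_seed(seed, "assoc"))
  stopifnot(effect_period %in% periods)
  k <- length(periods)
  z <- matrix(stats::rnorm(n * k), n, k)
  if (k > 1 && period_cor != 0) {
    for (j in 2:k) z[, j] <- period_cor * z[, j - 1] +
        sqrt(1 - period_cor^2) * z[, j]
  }
  expo <- exposure_mean + exposure_sd * z
  colnames(expo) <- periods
  cov <- gw_draw_covariates(n)
  lin <- 0.03 * (cov$maternal_age - 34.1) -
    0.4 * (cov$child_sex == "female") + 0.1 * stats::rnorm(n)
  outcome <- gamma * expo[, effect_period] / 10 + lin +
    stats::rnorm(n, 0, noise_sd)
  cov$birth_season <- factor(sample(c("cold", "warm"), n, replace = TRUE,
                                    prob = c(0.53, 0.47)),
                             levels = c("cold", "warm"))
  data <- cbind(data.frame(participant_id = sprintf("p%03d", seq_len(n)),
                           outcome = outcome - mean(outcome)), expo, cov)
  list(data = data, truth = list(gamma = gamma, period = effect_period))
}

#' Reduced-form cohort for distributed-lag calibration
#'
#' Weekly exposures on the unified 48-week axis (seasonal sine with a
#' per-participant conception offset plus AR(1) noise, floored at 0) and an
#' outcome responding to a planted lag profile confined to a window:
#' a raised-cosine bump peaked at the window centre (`shape = "cosine"`,
#' giving a well-defined peak week) or a flat windowed mean
#' (`shape = "flat"`, matching the cohort generator's construction). The
#' profile weights sum to 1, so `gamma` is weeks of outcome change per
#' 10-unit increase in the windowed weighted-mean exposure.
#'
#' @param n participants.
#' @param gamma planted effect, weeks per 10 units.
#' @param window planted unified-week window `c(start, end)`.
#' @param shape lag-profile shape within the window.
#' @param exposure_mean,amplitude,ar_sd,ar_rho weekly exposure process
#'   parameters.
#' @param noise_sd residual outcome SD, weeks.
#' @param n_lags lag-axis length.
#' @param seed RNG seed.
#' @return list: `weekly` (n x 48 matrix), `outcome`, `covariates`,
#'   `truth` (gamma, window, lag weights, peak week).
#' @export
simulate_dlm_cohort <- function(n = 150, gamma = -2, window = c(34, 44),
                                shape = c("cosine", "flat"),
                                exposure_mean = 26, amplitude = 5,
                                ar_sd = 4, ar_rho = 0.7, noise_sd = 1,
                                n_lags = 48, seed = 1) {
  shape <- match.arg(shape)
  set.seed(gw_stream_seed(seed, "dlm"))
  weeks <- seq_len(n_lags)
  X <- matrix(0, n, n_lags)
  offsets <- sample(0:51, n, replace = TRUE)
  for (i in seq_len(n)) {
    ar <- gw_ar1(n_lags, ar_rho, ar_sd)
    X[i, ] <- pmax(exposure_mean +
                     amplitude * sin(2 * pi * (weeks + offsets[i]) / 52) +
                     ar, 0)
  }
  w <- numeric(n_lags)
  span <- window[1]:window[2]
  if (shape == "cosine") {
    u <- (seq_along(span) - 0.5) / length(span)
    w[span] <- (1 - cos(2 * pi * u)) / 2
  } else {
    w[span] <- 1
  }
  w <- w / sum(w)
  cov <- gw_draw_covariates(n)
  lin <- 0.03 * (cov$maternal_age - 34.1) - 0.4 * (cov$child_sex == "female")
  outcome <- gamma * as.vector(X %*% w) / 10 + lin +
    stats::rnorm(n, 0, noise_sd)
  cov$birth_season <- factor(sample(c("cold", "warm"), n, replace = TRUE,
                                    prob = c(0.53, 0.47)),
                             levels = c("cold", "warm"))
  list(weekly = X, outcome = outcome - mean(outcome), covariates = cov,
       truth = list(gamma = gamma, window = window, weights = w,
                    peak_week = span[which.max(w[span])]))
}
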