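# Independent oracles and small fixture builders shared across tests.

# Brute-force inverse distance-squared weighted mean, written directly from
# the defining formula (independent of the package implementation).
oracle_idw <- function(values, distances_km, floor_km = 0.001) {
  d <- pmax(distances_km, floor_km)
  num <- 0; den <- 0
  for (i in seq_along(values)) {
    num <- num + values[i] / d[i]^2
    den <- den + 1 / d[i]^2
  }
  num / den
}

# Mean of a normal truncated to [lo, hi].
oracle_tnorm_mean <- function(mu, sd, lo, hi) {
  a <- (lo - mu) / sd; b <- (hi - mu) / sd
  mu + sd * (stats::dnorm(a) - stats::dnorm(b)) /
    (stats::pnorm(b) - stats::pnorm(a))
}

# Exhaustive grid search for a 2-type mixture on the simplex (step 0.001):
# independent oracle for the constrained-projection QP.
oracle_grid_2type <- function(b, R) {
  best <- c(NA, NA); best_obj <- Inf
  for (w1 in seq(0, 1, by = 0.001)) {
    for (w2 in seq(0, 1 - w1, by = 0.001)) {
      r <- b - R[, 1] * w1 - R[, 2] * w2
      obj <- sum(r^2)
      if (obj < best_obj) { best_obj <- obj; best <- c(w1, w2) }
    }
  }
  best
}

# Place stations at given distances (km) due north of a residence; along a
# meridian the haversine distance is exactly R * dlat, so distances are
# exact by construction.
stations_at_km <- function(km, lon0 = -76, lat0 = 39) {
  data.frame(station_id = sprintf("st%02d", seq_along(km)),
             longitude = lon0, latitude = lat0 + km / 111.19493,
             stringsAsFactors = FALSE)
}

# Minimal complete covariate table drawn from the fixed dictionary.
make_covariates <- function(n, seed = 1) {
  set.seed(seed)
  dict <- covariate_dictionary()
  out <- data.frame(maternal_age = round(runif(n, 20, 45), 1))
  for (nm in names(dict))
    out[[nm]] <- factor(sample(dict[[nm]], n, replace = TRUE),
                        levels = dict[[nm]])
  out
}

# A weekly station table with a constant value per station.
constant_station_weekly <- function(stations, pollutant, values,
                                    start = as.Date("2009-09-28"),
                                    n_weeks = 112) {
  do.call(rbind, lapply(seq_len(nrow(stations)), function(i) {
    data.frame(station_id = stations$station_id[i], pollutant = pollutant,
               week_start_date = start + 7 * (seq_len(n_weeks) - 1),
               value = values[i], stringsAsFactors = FALSE)
  }))
}
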