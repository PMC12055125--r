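# Exposure assignment: inverse distance-squared interpolation of weekly
# station measurements to maternal residences, on a unified weekly axis
# (weeks 1-13 = preconception, weeks 14 onward = pregnancy weeks 1, 2, ...),
# and period averages under the 10% missingness rule.

#' Great-circle distance between points, in kilometres
#'
#' Haversine distance on a sphere of radius 6371.0088 km (IUGG mean Earth
#' radius), adequate at the tens-of-kilometres scales of a monitoring
#' network.
#'
#' @param lon1,lat1 coordinates of the first point(s), decimal degrees.
#' @param lon2,lat2 coordinates of the second point(s), decimal degrees.
#' @return numeric vector of distances in km.
#' @export
haversine_km <- function(lon1, lat1, lon2, lat2) {
  geosphere::distHaversine(cbind(lon1, lat1), cbind(lon2, lat2),
                           r = 6371.0088)
}

#' Select the monitoring stations eligible for a residence
#'
#' Station-selection rule: if one or more stations lie within `near_km`
#' (5 km) of the residence, only those stations are used; otherwise up to
#' `max_n` (4) nearest stations within `max_km` (50 km) are used; if none,
#' the empty set is returned (the week is missing). Ties in distance are
#' broken by station id, lexicographically.
#'
#' @param lon,lat residence coordinates, decimal degrees.
#' @param stations data frame with columns `station_id`, `longitude`,
#'   `latitude`.
#' @param max_n cap on the number of stations outside the near ring.
#' @param near_km radius of the exclusive near ring, km.
#' @param max_km outer eligibility radius, km.
#' @return data frame with columns `station_id`, `distance_km`, ordered by
#'   distance; zero rows when no station is eligible.
#' @export
select_stations <- function(lon, lat, stations, max_n = 4,
                            near_km = 5, max_km = 50) {
  stopifnot(is.finite(lon), is.finite(lat),
            all(c("station_id", "longitude", "latitude") %in% names(stations)))
  d <- haversine_km(lon, lat, stations$longitude, stations$latitude)
  ord <- order(d, as.character(stations$station_id))
  out <- data.frame(station_id = as.character(stations$station_id)[ord],
                    distance_km = d[ord], stringsAsFactors = FALSE)
  near <- out$distance_km <= near_km
  if (any(near)) {
    out[near, , drop = FALSE]
  } else {
    eligible <- out[out$distance_km <= max_km, , drop = FALSE]
    utils::head(eligible, max_n)
  }
}

#' Inverse distance-squared interpolation
#'
#' Weighted mean of station values with weights 1/d^2. Distances below
#' `floor_km` are floored to it so a collocated station dominates without a
#' division by zero.
#'
#' @param values station concentrations (missing values are dropped together
#'   with their distances).
#' @param distances_km distances to the stations, km, same length.
#' @param floor_km minimum distance used in the weights.
#' @return interpolated concentration, or `NA_real_` when no value remains.
#' @export
idw_interpolate <- function(values, distances_km, floor_km = 0.001) {
  stopifnot(length(values) == length(distances_km))
  keep <- !is.na(values) & !is.na(distances_km)
  if (!any(keep)) return(NA_real_)
  v <- values[keep]
  d <- pmax(distances_km[keep], floor_km)
  w <- 1 / d^2
  sum(v * w) / sum(w)
}

#' Unified week axis for one pregnancy
#'
#' Weeks 1-13 are the 13 complete preconception weeks; week 14 is pregnancy
#' week 1. Pregnancy weeks extend to `ceiling(ga_weeks)`.
#'
#' @param ga_weeks gestational age at birth in weeks.
#' @return integer vector of unified week indices.
#' @export
unified_week_axis <- function(ga_weeks) {
  stopifnot(is.finite(ga_weeks), ga_weeks > 0)
  seq_len(13L + as.integer(ceiling(ga_weeks)))
}

# Start date (inclusive) of a unified week for a given conception date.
unified_week_start <- function(conception_date, week) {
  conception_date - 91L + 7L * (week - 1L)
}

#' Assign weekly exposures to one participant
#'
#' For every unified week, the stations eligible for the residence are
#' interpolated by inverse distance-squared weighting; the station week used
#' is the one whose 7-day span contains the participant week's midpoint.
#' Stations missing a value that week simply drop out of the weighted mean;
#' a week with no eligible station or no remaining value is missing.
#'
#' @param participant one-row data frame (or list) with `participant_id`,
#'   `longitude`, `latitude`, `conception_date` (Date), `ga_weeks`.
#' @param stations station table (`station_id`, `longitude`, `latitude`).
#' @param station_weekly long table: `station_id`, `pollutant`,
#'   `week_start_date` (Date), `value`.
#' @param pollutant pollutant name to extract.
#' @return data frame `participant_id`, `pollutant`, `unified_week`, `value`.
#' @export
assign_weekly_exposures <- function(participant, stations, station_weekly,
                                    pollutant) {
  ga <- as.numeric(participant$ga_weeks)
  if (!is.finite(ga) || ga < 20)
    stop("gestational age at birth below 20 weeks: implausible record for ",
         participant$participant_id)
  sel <- select_stations(participant$longitude, participant$latitude, stations)
  weeks <- unified_week_axis(ga)
  conception <- as.Date(participant$conception_date)
  out <- data.frame(
    participant_id = rep(as.character(participant$participant_id),
                         length(weeks)),
    pollutant = pollutant, unified_week = weeks, value = NA_real_,
    stringsAsFactors = FALSE
  )
  if (nrow(sel) == 0L) return(out)

  sw <- station_weekly[station_weekly$pollutant == pollutant &
                         station_weekly$station_id %in% sel$station_id, ,
                       drop = FALSE]
  if (nrow(sw) == 0L) return(out)
  grid_origin <- min(sw$week_start_date)
  sw_key <- paste(sw$station_id,
                  as.integer(sw$week_start_date - grid_origin) %/% 7L)
  value_by_key <- stats::setNames(sw$value, sw_key)

  midpoints <- unified_week_start(conception, weeks) + 3L
  bins <- as.integer(midpoints - grid_origin)
  ok <- bins >= 0L
  bins <- bins %/% 7L
  for (i in seq_along(weeks)) {
    if (!ok[i]) next
    keys <- paste(sel$station_id, bins[i])
    vals <- unname(value_by_key[keys])
    out$value[i] <- idw_interpolate(vals, sel$distance_km)
  }
  out
}

#' Assign weekly exposures to a whole cohort
#'
#' @param participants participant table (one residence per participant).
#' @inheritParams assign_weekly_exposures
#' @param pollutants character vector of pollutant names.
#' @return long data frame as in [assign_weekly_exposures()].
#' @export
assign_weekly_exposures_all <- function(participants, stations, station_weekly,
                                        pollutants) {
  pieces <- vector("list", nrow(participants) * length(pollutants))
  k <- 1L
  for (i in seq_len(nrow(participants))) {
    for (pol in pollutants) {
      pieces[[k]] <- assign_weekly_exposures(participants[i, ], stations,
                                             station_weekly, pol)
      k <- k + 1L
    }
  }
  do.call(rbind, pieces)
}

# Unified-week index sets for each exposure period. Trimester day ranges
# (1-90, 91-180, 181-birth) are mapped to pregnancy weeks by the
# majority-day rule, giving pregnancy weeks 1-13, 14-26, and 27-birth.
period_weeks <- function(period, ga_weeks) {
  last <- 13L + as.integer(ceiling(ga_weeks))
  switch(period,
    preconception = 1:13,
    pregnancy     = 14:last,
    trimester1    = 14:26,
    trimester2    = 27:39,
    trimester3    = 40:last,
    stop("unknown exposure period: ", period)
  )
}

#' Period average of a weekly exposure series
#'
#' Arithmetic mean of the non-missing weekly values in the period, reported
#' only when at most 10% of the period's weeks are missing (strict rule:
#' `missing_fraction > max_missing` yields a missing mean).
#'
#' @param series data frame with `unified_week` and `value` for one
#'   participant and pollutant (as returned by [assign_weekly_exposures()]),
#'   or a numeric vector indexed by unified week.
#' @param period one of `"preconception"`, `"pregnancy"`, `"trimester1"`,
#'   `"trimester2"`, `"trimester3"`.
#' @param ga_weeks gestational age at birth in weeks.
#' @param max_missing maximum tolerated missing fraction (default 0.10).
#' @return list with `mean`, `missing_fraction`, `n_weeks`.
#' @export
compute_period_average <- function(series, period, ga_weeks,
                                   max_missing = 0.10) {
  if (is.data.frame(series)) {
    values <- rep(NA_real_, max(series$unified_week))
    values[series$unified_week] <- series$value
  } else {
    values <- as.numeric(series)
  }
  wk <- period_weeks(period, ga_weeks)
  v <- rep(NA_real_, length(wk))
  in_range <- wk <= length(values)
  v[in_range] <- values[wk[in_range]]
  miss <- mean(is.na(v))
  list(mean = if (miss <= max_missing) mean(v, na.rm = TRUE) else NA_real_,
       missing_fraction = miss, n_weeks = length(wk))
}

#' Period-average table for a cohort
#'
#' @param weekly long weekly exposure table from
#'   [assign_weekly_exposures_all()].
#' @param participants participant table with `participant_id`, `ga_weeks`.
#' @param periods periods to compute (default all five).
#' @return long data frame: `participant_id`, `pollutant`, `period`, `value`,
#'   `missing_fraction`.
#' @export
period_average_table <- function(weekly, participants,
                                 periods = c("preconception", "pregnancy",
                                             "trimester1", "trimester2",
                                             "trimester3")) {
  ga <- stats::setNames(participants$ga_weeks,
                        as.character(participants$participant_id))
  combos <- unique(weekly[, c("participant_id", "pollutant")])
  rows <- vector("list", nrow(combos) * length(periods))
  k <- 1L
  for (i in seq_len(nrow(combos))) {
    pid <- combos$participant_id[i]
    pol <- combos$pollutant[i]
    ser <- weekly[weekly$participant_id == pid & weekly$pollutant == pol, ]
    for (per in periods) {
      pa <- compute_period_average(ser, per, ga[[pid]])
      rows[[k]] <- data.frame(participant_id = pid, pollutant = pol,
                              period = per, value = pa$mean,
                              missing_fraction = pa$missing_fraction,
                              stringsAsFactors = FALSE)
      k <- k + 1L
    }
  }
  do.call(rbind, rows)
}
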