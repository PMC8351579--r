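#' Parameters for the synthetic study-system generator
#'
#' Defaults emulate a continuous two-site acoustic monitoring campaign for a
#' spring-breeding chorusing anuran in the south-central US: recorders run
#' January through July for four years; hourly weather combines a seasonal
#' and diel temperature cycle with AR(1) noise, sparse gamma-distributed
#' rain events, a mean-reverting barometric-pressure walk (on the inches-of-
#' mercury scale typical of US station data), and a deterministic 29.53-day
#' moon cycle. Nightly chorus initiation follows a logistic model in night
#' temperature, 24-h cumulative precipitation and 24-h pressure change, with
#' a quadratic seasonal availability term peaking in mid-March; an initiated
#' night produces one or more contiguous bouts of detection-positive
#' 5-minute bins. Defaults are calibrated so that roughly 4% of recorded
#' bins are detection-positive, positives fall on a minority of dates, and
#' at least 95% of positives occur February–April.
#'
#' @param years Calendar years simulated.
#' @param n_sites Number of recorder sites.
#' @param season_start,season_end Recording span within each year
#'   (`"MM-DD"`).
#' @param temp_mean,temp_seasonal_amp Annual mean (°C) and seasonal
#'   half-range of daily-mean temperature.
#' @param temp_coldest_doy Day of year of the seasonal minimum.
#' @param temp_diel_amp Half-range of the within-day cycle (warmest 15:00).
#' @param temp_ar_phi,temp_ar_sd AR(1) coefficient and innovation SD of the
#'   hourly temperature noise.
#' @param rain_day_prob Probability a given day has a rain event.
#' @param rain_shape,rain_scale Gamma parameters of event totals (mm).
#' @param pressure_mean,pressure_theta,pressure_sd Mean, mean-reversion rate
#'   and hourly step SD of the pressure process (native pressure unit).
#' @param rh_base,rh_diel_amp,rh_rain_boost,rh_sd Relative-humidity model:
#'   baseline, diel half-range (most humid pre-dawn), boost applied when
#'   rain fell in the previous 24 h, and noise SD (percentage points).
#' @param wind_shape,wind_scale Gamma parameters of hourly wind speed
#'   (km/h).
#' @param moon_period,moon_phase0 Synodic period (days) and phase offset.
#' @param chorus_beta0,chorus_beta_temp,chorus_beta_precip,chorus_beta_dpress
#'   Logistic coefficients of nightly chorus initiation (intercept; per °C;
#'   per mm of 24-h precipitation; per pressure-unit of 24-h change).
#' @param chorus_peak_doy,chorus_season_scale Centre (day of year) and scale
#'   (days) of the quadratic seasonal availability penalty.
#' @param bout_extra_prob Each of up to two extra bouts occurs with this
#'   probability.
#' @param bout_len_mean Mean bout length in 5-minute bins (geometric).
#' @param bout_p_within Per-bin detection probability inside a bout.
#' @param dropout_prob Per-site-per-day recorder-failure probability (a
#'   failed day has no interval rows).
#' @param seed Integer seed; all generator randomness derives from it.
#' @return A `synthetic_params` list.
#' @export
synthetic_params <- function(years = 2015:2018,
                             n_sites = 2L,
                             season_start = "01-01",
                             season_end = "07-31",
                             temp_mean = 19.5,
                             temp_seasonal_amp = 9.5,
                             temp_coldest_doy = 15,
                             temp_diel_amp = 4,
                             temp_ar_phi = 0.98,
                             temp_ar_sd = 0.35,
                             rain_day_prob = 0.15,
                             rain_shape = 0.8,
                             rain_scale = 10,
                             pressure_mean = 29.5,
                             pressure_theta = 0.02,
                             pressure_sd = 0.02,
                             rh_base = 75,
                             rh_diel_amp = 15,
                             rh_rain_boost = 12,
                             rh_sd = 5,
                             wind_shape = 2,
                             wind_scale = 3.5,
                             moon_period = 29.53,
                             moon_phase0 = 0,
                             chorus_beta0 = -3.5,
                             chorus_beta_temp = 0.3,
                             chorus_beta_precip = 0.2,
                             chorus_beta_dpress = -8,
                             chorus_peak_doy = 75,
                             chorus_season_scale = 20,
                             bout_extra_prob = 0.7,
                             bout_len_mean = 60,
                             bout_p_within = 0.85,
                             dropout_prob = 0.25,
                             seed = 1L) {
  p <- as.list(environment())
  probs <- c(p$rain_day_prob, p$bout_extra_prob, p$bout_p_within,
    p$dropout_prob)
  if (any(probs < 0 | probs > 1)) {
    stop("probability parameters must be in [0, 1]", call. = FALSE)
  }
  if (any(c(p$temp_ar_sd, p$pressure_sd, p$rh_sd) < 0)) {
    stop("variance parameters must be non-negative", call. = FALSE)
  }
  if (p$bout_len_mean < 1) stop("bout_len_mean must be >= 1", call. = FALSE)
  structure(p, class = "synthetic_params")
}

season_dates <- function(params, year) {
  seq(
    as.Date(sprintf("%d-%s", year, params$season_start)),
    as.Date(sprintf("%d-%s", year, params$season_end)),
    by = "day"
  )
}

#' Generate synthetic hourly weather and moon illumination
#'
#' See [synthetic_params()] for the generative model. Reproducible: the same
#' parameter object (including its seed) always yields identical tables.
#'
#' @param params A `synthetic_params` object.
#' @return List with `env` (hourly tibble in the layout of
#'   [read_hourly_environment()], underived) and `moon` (per-date tibble).
#' @export
generate_environment <- function(params) {
  stopifnot(inherits(params, "synthetic_params"))
  set.seed(params$seed)

  env_years <- lapply(params$years, function(year) {
    dates <- season_dates(params, year)
    n_days <- length(dates)
    ts <- seq(
      lubridate::as_datetime(dates[1], tz = "UTC"),
      lubridate::as_datetime(dates[n_days], tz = "UTC") +
        lubridate::hours(23),
      by = "hour"
    )
    n <- length(ts)
    doy <- lubridate::yday(ts)
    hour <- lubridate::hour(ts)

    seasonal <- params$temp_mean - params$temp_seasonal_amp *
      cos(2 * pi * (doy - params$temp_coldest_doy) / 365)
    diel <- -params$temp_diel_amp * cos(2 * pi * (hour - 15) / 24)
    noise <- as.numeric(stats::filter(
      stats::rnorm(n, 0, params$temp_ar_sd),
      params$temp_ar_phi, method = "recursive"
    ))
    temp_c <- seasonal + diel + noise

    # Sparse rain: some days carry a gamma-distributed event spread over a
    # few consecutive hours.
    precip <- rep(0, n)
    rain_day <- stats::runif(n_days) < params$rain_day_prob
    for (d in which(rain_day)) {
      total <- stats::rgamma(1, params$rain_shape, scale = params$rain_scale)
      n_h <- 1L + stats::rpois(1, 3)
      start_h <- sample.int(24L, 1L) - 1L
      hrs <- (d - 1L) * 24L + start_h + seq_len(n_h) - 1L
      hrs <- hrs[hrs >= 1L & hrs <= n]
      if (length(hrs) > 0L) {
        w <- stats::rgamma(length(hrs), 1)
        precip[hrs] <- precip[hrs] + total * w / sum(w)
      }
    }

    # Mean-reverting pressure walk.
    pressure <- numeric(n)
    pressure[1] <- params$pressure_mean + stats::rnorm(1, 0, params$pressure_sd)
    steps <- stats::rnorm(n, 0, params$pressure_sd)
    for (i in seq_len(n - 1L)) {
      pressure[i + 1L] <- pressure[i] +
        params$pressure_theta * (params$pressure_mean - pressure[i]) +
        steps[i]
    }

    rain_recent <- as.numeric(stats::filter(
      precip > 0, rep(1, 24), method = "convolution", sides = 1
    ))
    rain_recent[is.na(rain_recent)] <- 0
    rh <- params$rh_base +
      params$rh_diel_amp * cos(2 * pi * (hour - 4) / 24) +
      params$rh_rain_boost * (rain_recent > 0) +
      stats::rnorm(n, 0, params$rh_sd)
    rh <- pmin(pmax(rh, 5), 100)

    wind <- stats::rgamma(n, params$wind_shape, scale = params$wind_scale)

    tibble::tibble(
      timestamp = ts, temp_c = temp_c, rh_pct = rh, wind_kmph = wind,
      pressure = pressure, precip_mm = precip
    )
  })
  env <- dplyr::bind_rows(env_years)

  all_dates <- sort(unique(as.Date(env$timestamp, tz = "UTC")))
  phase <- (as.numeric(all_dates) - params$moon_phase0) / params$moon_period
  moon <- tibble::tibble(
    date = all_dates,
    illumination = 0.5 * (1 - cos(2 * pi * phase))
  )
  list(env = env, moon = moon)
}

# Night bin index 0..143 maps to (date offset, minutes since midnight):
# 0..71 are 18:00-23:55 of the focal date, 72..143 are 00:00-05:55 of the
# next calendar date.
night_index_to_bin <- function(idx) {
  evening <- idx < 72L
  list(
    day_offset = ifelse(evening, 0L, 1L),
    bin_start = ifelse(evening, 1080L + 5L * idx, 5L * (idx - 72L))
  )
}

#' Generate synthetic chorus-activity interval records
#'
#' Simulates nightly chorus initiation over the environmental series and
#' emits the interval table the recorders would have produced, including
#' recorder-failure days (whole site-days with no rows). Conditions driving
#' initiation are evaluated at 21:00 of each date; bouts of contiguous
#' positive bins are placed within the night window (18:00 to 05:55 of the
#' following date).
#'
#' @param env Hourly environment from [generate_environment()] (underived is
#'   fine; features are derived internally).
#' @param moon Moon table (not a chorus driver by default, accepted for
#'   interface symmetry).
#' @param params A `synthetic_params` object.
#' @return An interval tibble (`site_id`, `date`, `bin_start`, `detected`)
#'   covering every recorded bin.
#' @export
generate_chorus_activity <- function(env, moon, params) {
  stopifnot(inherits(params, "synthetic_params"))
  set.seed(params$seed + 1L)

  feat <- derive_env_features(env)
  at21 <- feat[lubridate::hour(feat$timestamp) == 21L, , drop = FALSE]
  night <- tibble::tibble(
    date = as.Date(at21$timestamp, tz = "UTC"),
    temp_c = at21$temp_c,
    cum_precip_24h = dplyr::coalesce(at21$cum_precip_24h, 0),
    pressure_change_24h = dplyr::coalesce(at21$pressure_change_24h, 0)
  )
  doy <- lubridate::yday(night$date)
  logit <- params$chorus_beta0 +
    params$chorus_beta_temp * night$temp_c +
    params$chorus_beta_precip * night$cum_precip_24h +
    params$chorus_beta_dpress * night$pressure_change_24h -
    ((doy - params$chorus_peak_doy) / params$chorus_season_scale)^2
  night$p_init <- stats::plogis(logit)

  sites <- sprintf("S%d", seq_len(params$n_sites))
  all_dates <- sort(unique(as.Date(env$timestamp, tz = "UTC")))

  # Recorder coverage: full days minus per-site-per-day failures.
  coverage_keep <- matrix(
    stats::runif(length(sites) * length(all_dates)) >= params$dropout_prob,
    nrow = length(sites)
  )
  covered <- dplyr::bind_rows(lapply(seq_along(sites), function(s) {
    tibble::tibble(site_id = sites[s], date = all_dates[coverage_keep[s, ]])
  }))
  intervals <- tidyr::expand_grid(
    dplyr::arrange(covered, .data$site_id, .data$date),
    bin_start = seq(0L, 1435L, by = 5L)
  ) |>
    dplyr::mutate(detected = 0L) |>
    dplyr::arrange(.data$site_id, .data$date, .data$bin_start)

  # Nightly initiation per site, then bout placement on initiated nights.
  pos <- list()
  for (s in sites) {
    init <- stats::runif(nrow(night)) < night$p_init
    for (d in which(init)) {
      n_bouts <- 1L + stats::rbinom(1L, 2L, params$bout_extra_prob)
      for (b in seq_len(n_bouts)) {
        start <- sample.int(144L, 1L) - 1L
        len <- 1L + stats::rgeom(1L, 1 / params$bout_len_mean)
        idx <- start:min(start + len - 1L, 143L)
        hit <- idx[stats::runif(length(idx)) < params$bout_p_within]
        if (length(hit) == 0L) next
        loc <- night_index_to_bin(hit)
        pos[[length(pos) + 1L]] <- tibble::tibble(
          site_id = s,
          date = night$date[d] + loc$day_offset,
          bin_start = loc$bin_start
        )
      }
    }
  }

  if (length(pos) > 0L) {
    pos <- dplyr::distinct(dplyr::bind_rows(pos))
    key <- paste(intervals$site_id, intervals$date, intervals$bin_start)
    hit_key <- paste(pos$site_id, pos$date, pos$bin_start)
    intervals$detected[key %in% hit_key] <- 1L
  }
  intervals
}

#' Generate a complete synthetic dataset
#'
#' Convenience wrapper running [generate_environment()] and
#' [generate_chorus_activity()] with one parameter set.
#'
#' @param params A `synthetic_params` object.
#' @return List with `intervals`, `env` (underived) and `moon`.
#' @export
generate_dataset <- function(params = synthetic_params()) {
  e <- generate_environment(params)
  intervals <- generate_chorus_activity(e$env, e$moon, params)
  list(intervals = intervals, env = e$env, moon = e$moon)
}

#' Constant-rate interval table
#'
#' Every bin is independently detection-positive with probability `q` — the
#' simplest pool with a known detection probability, used as a simulator
#' oracle.
#'
#' @param q Per-bin detection probability.
#' @param n_dates Number of dates.
#' @param bins_per_date Bins per date (<= 288), laid out from midnight.
#' @param seed Integer seed.
#' @return An interval tibble for a single site `"S1"`.
#' @export
constant_rate_dataset <- function(q, n_dates, bins_per_date, seed = 1L) {
  stopifnot(q >= 0, q <= 1, bins_per_date >= 1, bins_per_date <= BINS_PER_DAY)
  set.seed(seed)
  out <- tidyr::expand_grid(
    site_id = "S1",
    date = as.Date("2015-01-01") + seq_len(n_dates) - 1L,
    bin_start = 5L * (seq_len(bins_per_date) - 1L)
  )
  out$detected <- stats::rbinom(nrow(out), 1L, q)
  out
}

#' Wrap an interval table as a pool directly
#'
#' Treats every date in the table as eligible — handy for simulator tests
#' and synthetic pools that skip the eligibility machinery.
#'
#' @param intervals Interval table.
#' @return An `interval_pool`.
#' @export
as_pool <- function(intervals) {
  build_pool(intervals, unique(intervals$date))
}
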