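#' Derive 24-hour environmental features
#'
#' Adds the two change-over-time features used for survey scheduling:
#' \describe{
#'   \item{`pressure_change_24h`}{`pressure(t) - pressure(t - 24 h)`, defined
#'     when the observation exactly 24 h earlier exists.}
#'   \item{`cum_precip_24h`}{total precipitation over the previous 24 hours,
#'     the window `[t - 24 h, t)` — the 24 hourly slots ending one hour
#'     before `t`, so the current hour's own precipitation is not included.}
#' }
#' Both features are missing (`NA`) for the first 24 h of the series. To
#' guard against gappy station data, `cum_precip_24h` additionally requires
#' at least 18 of the 24 hourly slots to be observed; with fewer the feature
#' is missing, and any threshold on a missing feature evaluates false.
#'
#' @param env Hourly environment tibble from [read_hourly_environment()] or
#'   [generate_environment()], sorted by timestamp.
#' @param min_hours Minimum observed hourly slots in the 24-h window for
#'   `cum_precip_24h` (default 18, i.e. 75%).
#' @return `env` with columns `pressure_change_24h` and `cum_precip_24h`
#'   appended.
#' @export
derive_env_features <- function(env, min_hours = 18L) {
  require_columns(env, c("timestamp", "pressure", "precip_mm"), "env")
  if (is.unsorted(env$timestamp, strictly = TRUE)) {
    stop("env must be sorted by timestamp with no duplicates", call. = FALSE)
  }
  if (nrow(env) == 0L) {
    return(dplyr::mutate(env,
      pressure_change_24h = numeric(0), cum_precip_24h = numeric(0)
    ))
  }

  # Work on a complete hourly grid so gaps are explicit.
  h <- as.integer(round(as.numeric(env$timestamp) / 3600))
  h0 <- min(h)
  pos <- h - h0 + 1L
  n_grid <- max(pos)
  precip_grid <- rep(0, n_grid)
  present <- rep(0L, n_grid)
  pressure_grid <- rep(NA_real_, n_grid)
  precip_grid[pos] <- dplyr::coalesce(env$precip_mm, 0)
  present[pos] <- as.integer(!is.na(env$precip_mm))
  pressure_grid[pos] <- env$pressure

  cs_precip <- c(0, cumsum(precip_grid))
  cs_present <- c(0L, cumsum(present))

  # Window [t-24h, t): grid slots pos-24 .. pos-1.
  lo <- pos - 24L
  cum <- ifelse(lo >= 1L, cs_precip[pos] - cs_precip[pmax(lo, 1L)], NA_real_)
  n_obs <- ifelse(lo >= 1L, cs_present[pos] - cs_present[pmax(lo, 1L)], 0L)
  cum[lo < 1L | n_obs < min_hours] <- NA_real_

  p24 <- ifelse(lo >= 1L, pressure_grid[pmax(lo, 1L)], NA_real_)
  dplyr::mutate(env,
    pressure_change_24h = .data$pressure - p24,
    cum_precip_24h = cum
  )
}

#' Summarise environmental conditions on detection-positive dates
#'
#' Computes, for each environmental variable, the six-number summary
#' (min, Q1, median, mean, Q3, max) over all hourly observations falling on
#' calendar dates with at least one detection-positive interval. Moon
#' illumination contributes one value per such date and is reported in
#' percent. Quantiles use linear interpolation between order statistics.
#'
#' @param intervals Interval table (any site; detection-positive dates are
#'   pooled across sites).
#' @param env Hourly environment with derived features
#'   (see [derive_env_features()]).
#' @param moon Moon table from [read_moon()].
#' @return A tibble with one row per variable and columns `variable`,
#'   `min`, `q1`, `median`, `mean`, `q3`, `max`. Empty (with a warning) if no
#'   date has a detection.
#' @export
summarize_detection_conditions <- function(intervals, env, moon) {
  validate_intervals(intervals)
  require_columns(env, c("timestamp", "temp_c", "rh_pct", "wind_kmph",
    "pressure", "precip_mm"), "env")

  pos_dates <- unique(intervals$date[intervals$detected == 1L])
  empty <- tibble::tibble(
    variable = character(0), min = numeric(0), q1 = numeric(0),
    median = numeric(0), mean = numeric(0), q3 = numeric(0), max = numeric(0)
  )
  if (length(pos_dates) == 0L) {
    warning("no detection-positive dates; empty summary", call. = FALSE)
    return(empty)
  }

  env_pos <- env[as.Date(env$timestamp, tz = "UTC") %in% pos_dates, ,
    drop = FALSE]

  vars <- c("temp_c", "rh_pct", "wind_kmph", "pressure",
    "pressure_change_24h", "precip_mm")
  vars <- intersect(vars, names(env_pos))
  values <- lapply(vars, function(v) stats::na.omit(env_pos[[v]]))
  names(values) <- vars
  if (!is.null(moon)) {
    require_columns(moon, c("date", "illumination"), "moon")
    values$moon_illumination_pct <-
      100 * moon$illumination[moon$date %in% pos_dates]
  }
  values <- values[vapply(values, length, 1L) > 0L]

  purrr::map_dfr(names(values), function(v) {
    x <- values[[v]]
    q <- sp_quantile(x, c(0, 0.25, 0.5, 0.75, 1))
    tibble::tibble(
      variable = v, min = q[1], q1 = q[2], median = q[3],
      mean = mean(x), q3 = q[4], max = q[5]
    )
  })
}
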