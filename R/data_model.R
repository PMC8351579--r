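#' Read verified detection events
#'
#' Reads a CSV of verified call-detection events, one row per event. The file
#' must have a header with columns `site_id`, `start_iso8601` and
#' `duration_s`. Timestamps are parsed as local clock time (stored as UTC so
#' no daylight-saving arithmetic is ever applied to them).
#'
#' @param path Path to a delimited text file.
#' @return A tibble with columns `site_id` (character), `start` (POSIXct) and
#'   `duration_s` (double, seconds), one row per event, in file order.
#' @export
read_detection_events <- function(path) {
  raw <- readr::read_csv(path,
    col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE
  )
  require_columns(raw, c("site_id", "start_iso8601", "duration_s"),
    "detection event file"
  )
  start <- lubridate::parse_date_time(
    raw$start_iso8601,
    orders = c("Ymd HMS", "Ymd HM"), tz = "UTC", quiet = TRUE
  )
  if (anyNA(start) && nrow(raw) > 0L) {
    bad <- which(is.na(start))[1L]
    stop(sprintf(
      "unparseable start timestamp %s on data line %d",
      dQuote(raw$start_iso8601[bad]), bad
    ), call. = FALSE)
  }
  duration_s <- suppressWarnings(as.numeric(raw$duration_s))
  if (anyNA(duration_s) && nrow(raw) > 0L) {
    bad <- which(is.na(duration_s))[1L]
    stop(sprintf("unparseable duration on data line %d", bad), call. = FALSE)
  }
  if (any(duration_s < 0)) {
    bad <- which(duration_s < 0)[1L]
    stop(sprintf("negative duration_s on data line %d", bad), call. = FALSE)
  }
  tibble::tibble(site_id = raw$site_id, start = start, duration_s = duration_s)
}

#' Enumerate recording coverage
#'
#' Builds the (site, date, bin) grid describing when recorders actually ran.
#' Binning only ever emits intervals inside this grid, so days or hours the
#' recorder missed never appear as silent false negatives.
#'
#' @param site_id Character vector of site labels.
#' @param dates `Date` vector of covered calendar dates (recycled over sites).
#' @param bins Integer minutes-since-midnight of covered 5-minute bins;
#'   defaults to the full day.
#' @return A tibble with columns `site_id`, `date`, `bin_start`.
#' @export
recording_coverage <- function(site_id, dates,
                               bins = seq(0L, 1435L, by = 5L)) {
  if (any(bins %% BIN_MINUTES != 0L) || any(bins < 0L) || any(bins > 1435L)) {
    stop("bins must be minutes-since-midnight on the 5-minute grid",
      call. = FALSE
    )
  }
  tidyr::expand_grid(
    site_id = unique(site_id),
    date = sort(unique(dates)),
    bin_start = sort(unique(as.integer(bins)))
  )
}

#' Bin detection events into 5-minute detection/non-detection intervals
#'
#' Summarises verified detection events as a binomial interval table: every
#' covered (site, date, bin) becomes one row, with `detected = 1` iff at
#' least one retained event overlaps the bin's half-open span
#' `[bin_start, bin_start + 5 min)`. Events no longer than `min_event_s`
#' seconds are discarded entirely before binning (short detections are
#' overwhelmingly false positives in automated classifier output). Bins are
#' aligned to the clock (hh:00, hh:05, ...); an event spanning a bin boundary
#' marks both bins, and an event crossing midnight contributes to both
#' calendar dates.
#'
#' @param events Tibble as returned by [read_detection_events()].
#' @param coverage Recording coverage as from [recording_coverage()]:
#'   every (site, date, bin) the recorder actually ran.
#' @param min_event_s Minimum event duration retained, seconds (strict:
#'   events with `duration_s <= min_event_s` are dropped). Default 3.
#' @return A tibble of interval records (`site_id`, `date`, `bin_start`,
#'   `detected`), one row per covered bin, sorted by site, date, bin. Events
#'   that overlap no covered bin are dropped with a warning; their count is
#'   in `attr(, "n_dropped_events")`.
#' @export
bin_events_to_intervals <- function(events, coverage, min_event_s = 3) {
  require_columns(events, c("site_id", "start", "duration_s"), "events")
  require_columns(coverage, c("site_id", "date", "bin_start"), "coverage")

  retained <- events[events$duration_s > min_event_s, , drop = FALSE]

  out <- coverage |>
    dplyr::distinct(.data$site_id, .data$date, .data$bin_start) |>
    dplyr::arrange(.data$site_id, .data$date, .data$bin_start) |>
    dplyr::mutate(detected = 0L)

  n_dropped <- 0L
  if (nrow(retained) > 0L) {
    # Expand each event to the set of 5-min clock bins its span overlaps,
    # working in epoch seconds so midnight crossings fall out naturally.
    s <- as.numeric(retained$start)
    e <- s + retained$duration_s
    step <- BIN_MINUTES * 60
    first <- floor(s / step)
    # Half-open span: an event ending exactly on a boundary does not touch
    # the next bin (0.1 ms slack; epoch seconds lack sub-us precision).
    last <- floor((e - 1e-4) / step)
    hit <- purrr::map_dfr(seq_len(nrow(retained)), function(i) {
      bin_epoch <- seq(first[i], last[i]) * step
      t <- as.POSIXct(bin_epoch, origin = "1970-01-01", tz = "UTC")
      tibble::tibble(
        event = i,
        site_id = retained$site_id[i],
        date = as.Date(t, tz = "UTC"),
        bin_start = as.integer(lubridate::hour(t)) * 60L +
          as.integer(lubridate::minute(t))
      )
    })
    hit <- dplyr::semi_join(hit, out, by = c("site_id", "date", "bin_start"))
    covered_events <- unique(hit$event)
    n_dropped <- nrow(retained) - length(covered_events)
    if (n_dropped > 0L) {
      warning(sprintf(
        "%d retained event(s) fall entirely outside declared coverage and were dropped",
        n_dropped
      ), call. = FALSE)
    }
    out <- out |>
      dplyr::rows_update(
        dplyr::distinct(hit, .data$site_id, .data$date, .data$bin_start) |>
          dplyr::mutate(detected = 1L),
        by = c("site_id", "date", "bin_start")
      )
  }
  attr(out, "n_dropped_events") <- n_dropped
  out
}

validate_intervals <- function(intervals, what = "interval table") {
  require_columns(intervals, c("site_id", "date", "bin_start", "detected"), what)
  if (any(intervals$bin_start %% BIN_MINUTES != 0L)) {
    stop(what, ": bin_start not on the 5-minute grid", call. = FALSE)
  }
  if (!all(intervals$detected %in% c(0L, 1L))) {
    bad <- which(!intervals$detected %in% c(0L, 1L))[1L]
    stop(sprintf(
      "%s: detected must be 0 or 1 (row %d has %s)",
      what, bad, intervals$detected[bad]
    ), call. = FALSE)
  }
  key <- paste(intervals$site_id, intervals$date, intervals$bin_start)
  if (anyDuplicated(key)) {
    stop(what, ": duplicated (site_id, date, bin_start)", call. = FALSE)
  }
  invisible(intervals)
}

#' Read or write an interval table
#'
#' The on-disk format is CSV with columns `site_id`, `date` (YYYY-MM-DD),
#' `bin_start` (HH:MM on the 5-minute grid) and `detected` (0/1). Write then
#' read reproduces the table exactly, values and row order.
#'
#' @param path File path.
#' @return `read_interval_table()`: a tibble of interval records.
#' @export
read_interval_table <- function(path) {
  raw <- readr::read_csv(path,
    col_types = readr::cols(
      site_id = readr::col_character(),
      date = readr::col_date(),
      bin_start = readr::col_character(),
      detected = readr::col_integer()
    ),
    progress = FALSE
  )
  require_columns(raw, c("site_id", "date", "bin_start", "detected"),
    "interval file"
  )
  out <- dplyr::mutate(raw, bin_start = parse_bin(.data$bin_start))
  validate_intervals(out, "interval file")
  out
}

#' @rdname read_interval_table
#' @param intervals A tibble of interval records.
#' @export
write_interval_table <- function(intervals, path) {
  validate_intervals(intervals)
  intervals |>
    dplyr::mutate(bin_start = format_bin(.data$bin_start)) |>
    readr::write_csv(path, progress = FALSE)
  invisible(path)
}

#' Read hourly environmental records
#'
#' Reads an hourly weather series (temperature, relative humidity, wind
#' speed, barometric pressure, hourly precipitation). Station files such as
#' NOAA's quality-controlled local climatological data can be adapted through
#' `col_map`. Barometric pressure is carried opaquely in the file's native
#' unit; every pressure threshold downstream is expressed in that same unit.
#' Missing observations are represented as absent rows (gaps), never as
#' zeros. The 24-h derived features are added later by
#' [derive_env_features()].
#'
#' @param path Path to a CSV with columns `timestamp_iso8601`, `temp_c`,
#'   `rh_pct`, `wind_kmph`, `pressure`, `precip_mm` (or names mapped via
#'   `col_map`).
#' @param col_map Optional named character vector mapping the standard names
#'   to the file's column names, e.g. `c(temp_c = "HourlyDryBulbTemperature")`.
#' @return A tibble sorted by `timestamp` (POSIXct, local clock time).
#' @export
read_hourly_environment <- function(path, col_map = NULL) {
  std <- c("timestamp_iso8601", "temp_c", "rh_pct", "wind_kmph",
    "pressure", "precip_mm")
  raw <- readr::read_csv(path,
    col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE
  )
  if (!is.null(col_map)) {
    for (nm in names(col_map)) {
      if (!col_map[[nm]] %in% names(raw)) {
        stop(sprintf(
          "environment file is missing mapped column %s (for %s)",
          dQuote(col_map[[nm]]), nm
        ), call. = FALSE)
      }
      names(raw)[names(raw) == col_map[[nm]]] <- nm
    }
  }
  require_columns(raw, std, "environment file")
  ts <- lubridate::parse_date_time(
    raw$timestamp_iso8601,
    orders = c("Ymd HMS", "Ymd HM", "Ymd H"), tz = "UTC", quiet = TRUE
  )
  if (anyNA(ts) && nrow(raw) > 0L) {
    bad <- which(is.na(ts))[1L]
    stop(sprintf("unparseable timestamp on data line %d", bad), call. = FALSE)
  }
  if (anyDuplicated(ts)) {
    stop("duplicated timestamp in environment file", call. = FALSE)
  }
  out <- tibble::tibble(
    timestamp = ts,
    temp_c = as.numeric(raw$temp_c),
    rh_pct = as.numeric(raw$rh_pct),
    wind_kmph = as.numeric(raw$wind_kmph),
    pressure = as.numeric(raw$pressure),
    precip_mm = as.numeric(raw$precip_mm)
  )
  if (any(out$rh_pct > 100 | out$rh_pct < 0, na.rm = TRUE)) {
    stop("rh_pct outside [0, 100] in environment file", call. = FALSE)
  }
  if (any(out$wind_kmph < 0, na.rm = TRUE)) {
    stop("negative wind_kmph in environment file", call. = FALSE)
  }
  if (any(out$precip_mm < 0, na.rm = TRUE)) {
    stop("negative precip_mm in environment file", call. = FALSE)
  }
  dplyr::arrange(out, .data$timestamp)
}

#' Read per-date moon illumination
#'
#' One row per calendar date with the illuminated fraction of the moon's
#' disk. Files on the percent scale (any value > 1) are detected
#' automatically and converted to fractions.
#'
#' @param path Path to a CSV with columns `date`, `illumination`.
#' @return A tibble with `date` (Date) and `illumination` (fraction in
#'   \[0, 1\]).
#' @export
read_moon <- function(path) {
  raw <- readr::read_csv(path,
    col_types = readr::cols(
      date = readr::col_date(),
      illumination = readr::col_double()
    ),
    progress = FALSE
  )
  require_columns(raw, c("date", "illumination"), "moon file")
  if (anyDuplicated(raw$date)) {
    stop("duplicated date in moon file", call. = FALSE)
  }
  illum <- raw$illumination
  if (any(illum > 1, na.rm = TRUE)) {
    illum <- illum / 100
  }
  if (any(illum < 0 | illum > 1, na.rm = TRUE)) {
    stop("moon illumination outside [0, 1] after scale detection",
      call. = FALSE
    )
  }
  tibble::tibble(date = raw$date, illumination = illum)
}
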