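test_that("detection-event reader parses rows, preserves order, and rejects bad input", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "site_id,start_iso8601,duration_s",
    "P1,2016-02-20T21:03:17,12.4",
    "P2,2016-02-21T03:10:00,4"
  ), path)
  ev <- read_detection_events(path)
  expect_equal(ev$site_id, c("P1", "P2"))
  expect_equal(ev$duration_s, c(12.4, 4))
  expect_equal(lubridate::hour(ev$start[1]), 21L)
  expect_equal(lubridate::second(ev$start[1]), 17)

  writeLines("site_id,start_iso8601,duration_s", path)
  expect_equal(nrow(read_detection_events(path)), 0L)

  writeLines(c("site_id,start,duration_s", "P1,2016-02-20T21:03:17,1"), path)
  expect_error(read_detection_events(path), "start_iso8601")

  writeLines(c(
    "site_id,start_iso8601,duration_s",
    "P1,2016-02-20T21:03:17,5",
    "P1,not-a-time,5"
  ), path)
  expect_error(read_detection_events(path), "line 2")

  writeLines(c("site_id,start_iso8601,duration_s", "P1,2016-02-20T21:03:17,-1"),
    path)
  expect_error(read_detection_events(path), "negative duration")
})

test_that("binning applies the 3-second filter and the half-open overlap rule", {
  cov <- recording_coverage("S1", as.Date("2016-02-20"),
    bins = seq(21 * 60L, 21 * 60L + 55L, by = 5L))

  short <- tibble::tibble(
    site_id = "S1",
    start = as.POSIXct("2016-02-20 21:02:00", tz = "UTC"),
    duration_s = 2.9
  )
  out <- bin_events_to_intervals(short, cov)
  expect_equal(sum(out$detected), 0L)
  expect_equal(nrow(out), 12L)

  # Exactly 3 s is excluded too (strict inequality).
  exact <- dplyr::mutate(short, duration_s = 3.0)
  expect_equal(sum(bin_events_to_intervals(exact, cov)$detected), 0L)

  spanning <- tibble::tibble(
    site_id = "S1",
    start = as.POSIXct("2016-02-20 21:04:58", tz = "UTC"),
    duration_s = 10
  )
  out <- bin_events_to_intervals(spanning, cov)
  hit <- out$bin_start[out$detected == 1L]
  expect_equal(hit, c(21L * 60L, 21L * 60L + 5L))

  none <- short[0, ]
  out <- bin_events_to_intervals(none, cov)
  expect_equal(nrow(out), 12L)
  expect_true(all(out$detected == 0L))

  # An event at a site/date outside coverage is dropped with a warning.
  stray <- tibble::tibble(
    site_id = "S9",
    start = as.POSIXct("2016-02-20 21:00:00", tz = "UTC"),
    duration_s = 60
  )
  expect_warning(out <- bin_events_to_intervals(stray, cov), "outside")
  expect_equal(attr(out, "n_dropped_events"), 1L)
  expect_true(all(out$detected == 0L))
})

test_that("an event crossing midnight marks bins on both calendar dates", {
  cov <- recording_coverage("S1", as.Date(c("2016-03-01", "2016-03-02")))
  ev <- tibble::tibble(
    site_id = "S1",
    start = as.POSIXct("2016-03-01 23:59:30", tz = "UTC"),
    duration_s = 60
  )
  out <- bin_events_to_intervals(ev, cov)
  hit <- out[out$detected == 1L, ]
  expect_equal(as.character(hit$date), c("2016-03-01", "2016-03-02"))
  expect_equal(hit$bin_start, c(1435L, 0L))
})

test_that("binned detections match brute-force interval overlap and re-binning is idempotent", {
  set.seed(41)
  dates <- as.Date("2016-02-10") + 0:2
  cov <- recording_coverage(c("A", "B"), dates,
    bins = seq(0L, 115L, by = 5L))
  events <- tibble::tibble(
    site_id = sample(c("A", "B"), 25, replace = TRUE),
    start = as.POSIXct("2016-02-10 00:00:00", tz = "UTC") +
      round(stats::runif(25, 0, 3 * 7200)),
    duration_s = round(stats::runif(25, 0, 400), 1)
  )
  out <- suppressWarnings(bin_events_to_intervals(events, cov))
  expect_equal(out$detected, as.integer(brute_force_overlap(events, cov)))

  # Re-binning each positive bin as a 300-s event reproduces the flags.
  pos <- out[out$detected == 1L, ]
  as_events <- tibble::tibble(
    site_id = pos$site_id,
    start = as.POSIXct(
      paste(pos$date, format_hm(pos$bin_start)), tz = "UTC"
    ),
    duration_s = 300
  )
  again <- bin_events_to_intervals(as_events, cov)
  expect_equal(again$detected, out$detected)
})

test_that("interval tables round-trip through CSV exactly", {
  set.seed(7)
  tab <- constant_rate_dataset(0.3, n_dates = 5, bins_per_date = 20, seed = 2)
  path <- withr::local_tempfile(fileext = ".csv")
  write_interval_table(tab, path)
  expect_equal(read_interval_table(path), tab)

  writeLines(c(
    "site_id,date,bin_start,detected",
    "S1,2016-02-01,00:00,2"
  ), path)
  expect_error(read_interval_table(path), "0 or 1")

  writeLines("site_id,date,bin_start,detected", path)
  expect_equal(nrow(read_interval_table(path)), 0L)

  writeLines(c(
    "site_id,date,bin_start,detected",
    "S1,2016-02-01,00:03,0"
  ), path)
  expect_error(read_interval_table(path), "5-minute grid")
})

test_that("environment and moon readers validate and auto-detect scales", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "timestamp_iso8601,temp_c,rh_pct,wind_kmph,pressure,precip_mm",
    "2016-02-01T00:00:00,10,80,5,29.5,0",
    "2016-02-01T02:00:00,11,82,6,29.4,1.2"
  ), path)
  env <- read_hourly_environment(path)
  expect_equal(nrow(env), 2L)
  expect_equal(env$precip_mm, c(0, 1.2))

  # Column mapping adapts station files with other headers.
  writeLines(c(
    "DATE,DryBulb,RH,Wind,Press,Precip",
    "2016-02-01T00:00:00,10,80,5,29.5,0"
  ), path)
  env <- read_hourly_environment(path, col_map = c(
    timestamp_iso8601 = "DATE", temp_c = "DryBulb", rh_pct = "RH",
    wind_kmph = "Wind", pressure = "Press", precip_mm = "Precip"
  ))
  expect_equal(env$temp_c, 10)

  writeLines(c(
    "timestamp_iso8601,temp_c,rh_pct,wind_kmph,pressure,precip_mm",
    "2016-02-01T00:00:00,10,101,5,29.5,0"
  ), path)
  expect_error(read_hourly_environment(path), "rh_pct")

  writeLines(c(
    "timestamp_iso8601,temp_c,rh_pct,wind_kmph,pressure,precip_mm",
    "2016-02-01T00:00:00,10,80,5,29.5,0",
    "2016-02-01T00:00:00,11,81,5,29.5,0"
  ), path)
  expect_error(read_hourly_environment(path), "duplicated timestamp")

  writeLines(c("date,illumination", "2016-02-01,91", "2016-02-02,12"), path)
  moon <- read_moon(path)
  expect_equal(moon$illumination, c(0.91, 0.12))

  writeLines(c("date,illumination", "2016-02-01,0.5"), path)
  expect_equal(read_moon(path)$illumination, 0.5)

  writeLines(c("date,illumination", "2016-02-01,0.5", "2016-02-01,0.6"), path)
  expect_error(read_moon(path), "duplicated date")
})
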