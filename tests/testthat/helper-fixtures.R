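# Fixture builders and independent oracles shared across the suite.

# A compact interval table from a per-date detection layout:
# layout is a named list date -> integer vector of detected flags laid out
# on consecutive 5-minute bins from `first_bin`.
intervals_from_layout <- function(layout, site_id = "S1", first_bin = 0L) {
  dplyr::bind_rows(lapply(names(layout), function(d) {
    det <- as.integer(layout[[d]])
    tibble::tibble(
      site_id = site_id,
      date = as.Date(d),
      bin_start = first_bin + 5L * (seq_along(det) - 1L),
      detected = det
    )
  }))
}

# Hourly environment with given variable columns, one row per hour over
# consecutive dates starting at `start`.
env_from_values <- function(values, start = "2016-02-01 00:00:00") {
  n <- length(values[[1]])
  base <- tibble::tibble(
    timestamp = as.POSIXct(start, tz = "UTC") + 3600 * (seq_len(n) - 1L),
    temp_c = 20, rh_pct = 80, wind_kmph = 5, pressure = 29.5, precip_mm = 0
  )
  for (nm in names(values)) base[[nm]] <- values[[nm]]
  base
}

# Brute-force count of 5-minute bins overlapped by retained events:
# scans every (bin, event) pair directly.
brute_force_overlap <- function(events, coverage, min_event_s = 3) {
  kept <- events[events$duration_s > min_event_s, , drop = FALSE]
  hit <- logical(nrow(coverage))
  for (i in seq_len(nrow(coverage))) {
    b0 <- as.POSIXct(
      paste(coverage$date[i], format_hm(coverage$bin_start[i])),
      tz = "UTC"
    )
    b1 <- b0 + 300
    for (j in seq_len(nrow(kept))) {
      if (kept$site_id[j] != coverage$site_id[i]) next
      e0 <- kept$start[j]
      e1 <- e0 + kept$duration_s[j]
      if (e0 < b1 && e1 > b0) hit[i] <- TRUE
    }
  }
  hit
}

format_hm <- function(m) sprintf("%02d:%02d", m %/% 60L, m %% 60L)

# Exhaustive threshold-search oracle: nested loops over every candidate
# choice, scanning hourly rows per date, then ranked by the documented
# total order. Independent of grid_search's vectorised path.
brute_force_search <- function(intervals, env, cand, min_dates = 0L) {
  env_dates <- as.Date(env$timestamp, tz = "UTC")
  vars <- names(cand)
  choice_sets <- lapply(cand, function(tb) seq_len(nrow(tb)))
  idx_grid <- expand.grid(choice_sets, KEEP.OUT.ATTRS = FALSE)
  rows <- list()
  for (ci in seq_len(nrow(idx_grid))) {
    ok_hour <- rep(TRUE, nrow(env))
    desc <- character(0)
    for (v in vars) {
      ch <- cand[[v]][idx_grid[ci, v][[1]], ]
      x <- env[[v]]
      this <- if (ch$direction == "greater_than") x > ch$value else x < ch$value
      this[is.na(this)] <- FALSE
      ok_hour <- ok_hour & this
      op <- if (ch$direction == "greater_than") ">" else "<"
      desc <- c(desc, sprintf("%s %s %g", v, op, ch$value))
    }
    elig <- unique(env_dates[ok_hour])
    sub <- intervals[intervals$date %in% elig, , drop = FALSE]
    n_pos <- sum(sub$detected == 1L)
    n_neg <- sum(sub$detected == 0L)
    rows[[ci]] <- tibble::tibble(
      rules = paste(desc, collapse = " & "),
      n_dates = length(unique(sub$date)),
      n_pos = n_pos, n_neg = n_neg,
      ratio = if (n_pos + n_neg == 0L) {
        NA_real_
      } else if (n_neg == 0L) Inf else n_pos / n_neg
    )
  }
  out <- dplyr::bind_rows(rows)
  out <- out[out$n_dates >= min_dates, , drop = FALSE]
  out[order(-out$ratio, -out$n_pos, -out$n_dates, out$rules, na.last = TRUE), ]
}
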