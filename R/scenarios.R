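SCENARIO_VARIABLES <- c(
  "temp_c", "rh_pct", "wind_kmph", "pressure", "moon_illumination",
  "pressure_change_24h", "cum_precip_24h", "precip_mm"
)

#' Define an environmental threshold rule
#'
#' A single scheduling rule of the form `variable > value` or
#' `variable < value`. Rules are combined into scenarios; a calendar date is
#' surveyable under a scenario when its rules are met at some point within
#' the date (see [eligible_dates()]).
#'
#' @param variable One of `r paste0('\x60', SCENARIO_VARIABLES, '\x60', collapse = ", ")`.
#' @param direction `"greater_than"` or `"less_than"`.
#' @param value Threshold, in the variable's own unit (moon illumination as a
#'   fraction of full).
#' @return A one-row tibble; bind rows to build a rule set.
#' @export
threshold_rule <- function(variable,
                           direction = c("greater_than", "less_than"),
                           value) {
  direction <- match.arg(direction)
  if (!variable %in% SCENARIO_VARIABLES) {
    stop(sprintf(
      "unknown rule variable %s (known: %s)",
      dQuote(variable), paste(SCENARIO_VARIABLES, collapse = ", ")
    ), call. = FALSE)
  }
  if (!is.finite(value)) stop("rule value must be finite", call. = FALSE)
  tibble::tibble(variable = variable, direction = direction, value = value)
}

no_rules <- function() {
  tibble::tibble(
    variable = character(0), direction = character(0), value = numeric(0)
  )
}

#' Define a survey scenario
#'
#' A scenario names the rule set that decides which dates and times are
#' surveyable: the calendar months surveyed, the nightly listening window,
#' and zero or more environmental threshold rules. Because surveys are
#' scheduled in advance from forecasts, eligibility is per calendar date: if
#' the thresholds are met at any point within a date, every night interval of
#' that date may be surveyed.
#'
#' @param name Scenario label.
#' @param months Integer months surveyed (default February–April, the peak
#'   chorusing period).
#' @param night_start,morning_end Clock times (`"HH:MM"` or minutes since
#'   midnight) bounding the nightly window: a bin is surveyable when it
#'   starts at/after `night_start` or strictly before `morning_end`.
#' @param rules Tibble of threshold rules ([threshold_rule()] rows), possibly
#'   empty.
#' @param simultaneous If `TRUE` (default) a date qualifies when all rules
#'   hold at the same hourly observation; if `FALSE`, when each rule holds at
#'   some (possibly different) hour of the date.
#' @return An object of class `survey_scenario`.
#' @seealso [scenario_random()], [scenario_usfws()], [scenario_optimized()]
#' @export
scenario <- function(name, months = 2:4,
                     night_start = "18:00", morning_end = "06:00",
                     rules = no_rules(), simultaneous = TRUE) {
  months <- as.integer(months)
  if (!all(months %in% 1:12)) stop("months must be in 1..12", call. = FALSE)
  as_minutes <- function(x) if (is.character(x)) parse_bin(x) else as.integer(x)
  structure(
    list(
      name = name, months = sort(unique(months)),
      night_start = as_minutes(night_start),
      morning_end = as_minutes(morning_end),
      rules = rules, simultaneous = isTRUE(simultaneous)
    ),
    class = "survey_scenario"
  )
}

#' @export
print.survey_scenario <- function(x, ...) {
  cat(sprintf(
    "<survey_scenario> %s\n  months: %s, window: >= %s or < %s\n  rules: %s\n",
    x$name, paste(x$months, collapse = ","),
    format_bin(x$night_start), format_bin(x$morning_end),
    describe_rules(x$rules)
  ))
  invisible(x)
}

#' Predefined survey scenarios
#'
#' Three named rule sets: `scenario_random()` imposes no environmental
#' thresholds (any peak-period night interval is surveyable);
#' `scenario_usfws()` applies the federal survey-protocol conditions for the
#' Houston Toad (temperature > 14 °C, relative humidity > 70%, wind
#' < 24 km/h, moon illumination < 0.5 of full); `scenario_optimized()`
#' applies the threshold combination found by [grid_search()] to maximise
#' the detection:non-detection ratio (temperature > 16 °C, positive 24-h
#' cumulative precipitation, 24-h barometric-pressure fall below −0.07 in
#' the pressure series' native unit).
#'
#' @return A `survey_scenario`.
#' @export
scenario_random <- function() {
  scenario("random")
}

#' @rdname scenario_random
#' @export
scenario_usfws <- function() {
  scenario("usfws", rules = dplyr::bind_rows(
    threshold_rule("temp_c", "greater_than", 14),
    threshold_rule("rh_pct", "greater_than", 70),
    threshold_rule("wind_kmph", "less_than", 24),
    threshold_rule("moon_illumination", "less_than", 0.5)
  ))
}

#' @rdname scenario_random
#' @export
scenario_optimized <- function() {
  scenario("optimized", rules = dplyr::bind_rows(
    threshold_rule("temp_c", "greater_than", 16),
    threshold_rule("cum_precip_24h", "greater_than", 0),
    threshold_rule("pressure_change_24h", "less_than", -0.07)
  ))
}

#' Restrict intervals to the peak chorusing period
#'
#' Keeps interval records in the stated months whose bin starts in the
#' nightly window (strictly before `morning_end`, or at/after
#' `night_start`).
#'
#' @param intervals Interval table.
#' @param months Months retained (default February–April).
#' @param night_start,morning_end Window bounds as `"HH:MM"` or minutes.
#' @return The filtered interval table.
#' @export
peak_period_filter <- function(intervals, months = 2:4,
                               night_start = "18:00", morning_end = "06:00") {
  validate_intervals(intervals)
  as_minutes <- function(x) if (is.character(x)) parse_bin(x) else as.integer(x)
  ns <- as_minutes(night_start)
  me <- as_minutes(morning_end)
  dplyr::filter(
    intervals,
    lubridate::month(.data$date) %in% months,
    .data$bin_start < me | .data$bin_start >= ns
  )
}

# Join per-date moon illumination onto hourly env rows and evaluate one rule
# as an hourly logical; missing feature values evaluate FALSE.
augment_env <- function(env, moon) {
  out <- dplyr::mutate(env, ..date = as.Date(.data$timestamp, tz = "UTC"))
  if (!is.null(moon)) {
    out <- dplyr::left_join(
      out,
      dplyr::rename(moon, moon_illumination = "illumination"),
      by = c("..date" = "date")
    )
  }
  out
}

eval_rule_hourly <- function(env_aug, variable, direction, value) {
  if (!variable %in% names(env_aug)) {
    stop(sprintf(
      "rule variable %s is not available in the environmental data%s",
      dQuote(variable),
      if (variable == "moon_illumination") " (no moon table supplied)" else ""
    ), call. = FALSE)
  }
  v <- env_aug[[variable]]
  ok <- if (direction == "greater_than") v > value else v < value
  ok & !is.na(ok)
}

#' Dates on which a rule set is satisfied
#'
#' A calendar date is eligible when at least one hourly observation on that
#' date satisfies the rules — all of them at the same observation under the
#' default simultaneous semantics, or each at some (possibly different) hour
#' when `simultaneous = FALSE`. Moon illumination is constant over a date.
#' An empty rule set makes every date with any environmental coverage
#' eligible. Thresholds on a missing feature value evaluate false at that
#' hour.
#'
#' @param env Hourly environment, with derived features where rules need
#'   them.
#' @param moon Moon table, required when a rule references
#'   `moon_illumination`; otherwise may be `NULL`.
#' @param rules Tibble of threshold rules (possibly empty).
#' @param simultaneous Rule-combination semantics (see above).
#' @return A sorted `Date` vector.
#' @export
eligible_dates <- function(env, moon = NULL, rules = no_rules(),
                           simultaneous = TRUE) {
  require_columns(env, "timestamp", "env")
  env_aug <- augment_env(env, moon)
  if (nrow(rules) == 0L) {
    return(sort(unique(env_aug$..date)))
  }
  per_rule <- lapply(seq_len(nrow(rules)), function(i) {
    eval_rule_hourly(env_aug, rules$variable[i], rules$direction[i],
      rules$value[i])
  })
  dates <- env_aug$..date
  if (simultaneous) {
    all_ok <- Reduce(`&`, per_rule)
    keep <- unique(dates[all_ok])
  } else {
    per_rule_dates <- lapply(per_rule, function(ok) unique(dates[ok]))
    keep <- Reduce(intersect, per_rule_dates)
    keep <- as.Date(keep, origin = "1970-01-01")
  }
  sort(keep)
}

#' Build the pool of surveyable intervals
#'
#' Restricts a (peak-period-filtered) interval table to eligible dates and
#' wraps it as an `interval_pool`, the sampling frame for the survey
#' simulator.
#'
#' @param intervals Interval table, already passed through
#'   [peak_period_filter()].
#' @param eligible `Date` vector of surveyable dates (from
#'   [eligible_dates()]).
#' @return An `interval_pool`: list with `intervals` (tibble), `dates`
#'   (sorted eligible dates actually present) and `empty` flag.
#' @export
build_pool <- function(intervals, eligible) {
  validate_intervals(intervals)
  pool_int <- dplyr::filter(intervals, .data$date %in% eligible) |>
    dplyr::arrange(.data$date, .data$site_id, .data$bin_start)
  structure(
    list(
      intervals = pool_int,
      dates = sort(unique(pool_int$date)),
      empty = nrow(pool_int) == 0L
    ),
    class = "interval_pool"
  )
}

#' @export
print.interval_pool <- function(x, ...) {
  cat(sprintf(
    "<interval_pool> %d intervals on %d dates (%d positive)%s\n",
    nrow(x$intervals), length(x$dates), sum(x$intervals$detected),
    if (x$empty) " [empty]" else ""
  ))
  invisible(x)
}

#' Apply a scenario end to end
#'
#' Convenience wrapper: peak-period filter with the scenario's months and
#' nightly window, compute eligible dates from its rules, and build the
#' interval pool.
#'
#' @param intervals Full interval table.
#' @param env Hourly environment with derived features.
#' @param moon Moon table (or `NULL` when no rule needs it).
#' @param scn A `survey_scenario`.
#' @return An `interval_pool`.
#' @export
scenario_pool <- function(intervals, env, moon, scn) {
  stopifnot(inherits(scn, "survey_scenario"))
  peak <- peak_period_filter(intervals,
    months = scn$months,
    night_start = scn$night_start, morning_end = scn$morning_end
  )
  ok <- eligible_dates(env, moon, scn$rules, simultaneous = scn$simultaneous)
  build_pool(peak, ok)
}
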