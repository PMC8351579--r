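test_that("peak-period filter keeps February-April night bins", {
  ints <- tibble::tibble(
    site_id = "S1",
    date = as.Date(c("2016-02-01", "2016-03-03", "2016-05-01", "2016-02-01")),
    bin_start = c(355L, 720L, 1320L, 360L), # 05:55, 12:00, 22:00, 06:00
    detected = 0L
  )
  out <- peak_period_filter(ints)
  expect_equal(nrow(out), 1L)
  expect_equal(out$bin_start, 355L) # 05:55 retained; 06:00, noon, May dropped

  # Boundary at 18:00 is inside the window.
  evening <- tibble::tibble(
    site_id = "S1", date = as.Date("2016-03-01"),
    bin_start = c(1075L, 1080L), detected = 0L
  )
  expect_equal(peak_period_filter(evening)$bin_start, 1080L)
})

test_that("date eligibility follows the any-point-within-a-date rule", {
  usfws <- scenario_usfws()
  env <- env_from_values(
    list(temp_c = 15, rh_pct = 80, wind_kmph = 10),
    start = "2016-02-10 21:00:00"
  )
  moon <- tibble::tibble(date = as.Date("2016-02-10"), illumination = 0.2)
  expect_equal(
    eligible_dates(env, moon, usfws$rules),
    as.Date("2016-02-10")
  )

  cold <- dplyr::mutate(env, temp_c = 14) # threshold is strict
  expect_length(eligible_dates(cold, moon, usfws$rules), 0L)

  # Empty rule set: every date with any coverage.
  expect_equal(eligible_dates(env, moon), as.Date("2016-02-10"))
})

test_that("simultaneous and per-rule-independent semantics differ as designed", {
  # Hour 1 is warm but dry, hour 2 wet but cold: no single hour satisfies
  # both rules, but each rule is satisfied at some hour of the date.
  env <- env_from_values(
    list(temp_c = c(20, 5), cum_precip_24h = c(0, 3)),
    start = "2016-02-10 20:00:00"
  )
  rules <- dplyr::bind_rows(
    threshold_rule("temp_c", "greater_than", 14),
    threshold_rule("cum_precip_24h", "greater_than", 1)
  )
  expect_length(eligible_dates(env, NULL, rules, simultaneous = TRUE), 0L)
  expect_equal(
    eligible_dates(env, NULL, rules, simultaneous = FALSE),
    as.Date("2016-02-10")
  )

  expect_error(
    eligible_dates(env, NULL, dplyr::bind_rows(
      rules, threshold_rule("moon_illumination", "less_than", 0.5)
    )),
    "moon_illumination"
  )
})

test_that("adding rules never enlarges the eligible-date set", {
  set.seed(5)
  params <- synthetic_params(years = 2016, seed = 5L)
  e <- generate_environment(params)
  env <- derive_env_features(e$env)
  rule_pool <- dplyr::bind_rows(
    threshold_rule("temp_c", "greater_than", 14),
    threshold_rule("rh_pct", "greater_than", 70),
    threshold_rule("wind_kmph", "less_than", 24),
    threshold_rule("moon_illumination", "less_than", 0.5),
    threshold_rule("cum_precip_24h", "greater_than", 0),
    threshold_rule("pressure_change_24h", "less_than", -0.05)
  )
  for (i in seq_len(10)) {
    n_rules <- sample(0:5, 1)
    rules <- rule_pool[sample.int(nrow(rule_pool), n_rules), ]
    base <- eligible_dates(env, e$moon, rules)
    extra <- rule_pool[sample.int(nrow(rule_pool), 1), ]
    tighter <- eligible_dates(env, e$moon, dplyr::bind_rows(rules, extra))
    expect_true(all(tighter %in% base))
  }
})

test_that("scenario pools nest: no-rule pool contains every thresholded pool", {
  d <- generate_dataset(synthetic_params(years = 2016, seed = 9L))
  env <- derive_env_features(d$env)
  pool_random <- scenario_pool(d$intervals, env, d$moon, scenario_random())
  pool_usfws <- scenario_pool(d$intervals, env, d$moon, scenario_usfws())
  pool_opt <- scenario_pool(d$intervals, env, d$moon, scenario_optimized())

  key <- function(p) {
    paste(p$intervals$site_id, p$intervals$date, p$intervals$bin_start)
  }
  expect_true(all(key(pool_usfws) %in% key(pool_random)))
  expect_true(all(key(pool_opt) %in% key(pool_random)))
  expect_true(all(pool_usfws$dates %in% pool_random$dates))

  # Pool bookkeeping: interval count equals the per-date sum, dates sorted.
  per_date <- table(pool_usfws$intervals$date)
  expect_equal(sum(per_date), nrow(pool_usfws$intervals))
  expect_false(is.unsorted(pool_usfws$dates))
})

test_that("build_pool restricts exactly to eligible dates", {
  ints <- constant_rate_dataset(0.5, n_dates = 10, bins_per_date = 6, seed = 3)
  all_dates <- unique(ints$date)

  identity_pool <- build_pool(ints, all_dates)
  expect_equal(identity_pool$intervals, dplyr::arrange(ints, date, site_id, bin_start))

  some <- build_pool(ints, all_dates[c(1, 4, 7)])
  expect_length(some$dates, 3L)
  expect_equal(nrow(some$intervals), 18L)

  none <- build_pool(ints, as.Date(character(0)))
  expect_true(none$empty)
})
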