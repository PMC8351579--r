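test_that("candidate grids emit unique values in both directions", {
  env <- env_from_values(list(temp_c = c(1, 2, 2, 3)))
  cand <- candidate_grid(env, "temp_c")
  expect_equal(sort(unique(cand$temp_c$value)), c(1, 2, 3))
  expect_equal(nrow(cand$temp_c), 6L)

  # Decimation caps the candidate count at quantile points.
  env_big <- env_from_values(list(temp_c = seq_len(1000)))
  cand_big <- candidate_grid(env_big, "temp_c", resolution = 11)
  expect_lte(length(unique(cand_big$temp_c$value)), 11L)

  const <- candidate_grid(env_from_values(list(temp_c = rep(7, 5))), "temp_c")
  expect_equal(nrow(const$temp_c), 2L)

  expect_error(candidate_grid(env, "not_a_var"), "not_a_var")
})

test_that("combo evaluation counts pools and flags degenerate ratios", {
  # 10 positive / 90 negative intervals over two dates, no rules.
  ints <- intervals_from_layout(list(
    `2016-02-01` = c(rep(1, 10), rep(0, 40)),
    `2016-02-02` = rep(0, 50)
  ))
  env <- env_from_values(list(temp_c = c(10, 20)),
    start = "2016-02-01 12:00:00")
  env$timestamp[2] <- as.POSIXct("2016-02-02 12:00:00", tz = "UTC")
  combo <- evaluate_combo(ints, env)
  expect_equal(combo$n_dates, 2L)
  expect_equal(combo$n_pos, 10L)
  expect_equal(combo$ratio, 10 / 90)

  # A rule excluding every date: empty pool, undefined ratio.
  none <- evaluate_combo(ints, env,
    rules = threshold_rule("temp_c", "greater_than", 99))
  expect_equal(none$n_dates, 0L)
  expect_true(is.na(none$ratio))
})

test_that("perfect separation is found and flagged as an infinite ratio", {
  # Positives only on warm dates (> 20 deg), negatives only on cold ones.
  ints <- intervals_from_layout(list(
    `2016-02-01` = rep(1, 5), `2016-02-02` = rep(0, 5),
    `2016-02-03` = rep(1, 5), `2016-02-04` = rep(0, 5)
  ))
  env <- env_from_values(
    list(temp_c = c(25, 15, 24, 14), cum_precip_24h = c(1, 1, 1, 1)),
    start = "2016-02-01 12:00:00"
  )
  env$timestamp <- as.POSIXct(
    paste(as.Date("2016-02-01") + 0:3, "12:00:00"), tz = "UTC"
  )
  top <- grid_search(ints, env, variables = "temp_c", top_n = 1)
  expect_equal(top$ratio, Inf)
  expect_equal(top$n_pos, 10L)
  expect_match(top$rules, "temp_c > ")
})

test_that("grid search equals exhaustive enumeration on a 3x3x3 toy problem", {
  set.seed(77)
  n_dates <- 8
  dates <- as.Date("2016-02-01") + seq_len(n_dates) - 1
  # Three variables, each taking exactly 3 distinct values across hours.
  env <- env_from_values(
    list(
      temp_c = sample(c(10, 16, 22), n_dates * 4, replace = TRUE),
      cum_precip_24h = sample(c(0, 2, 5), n_dates * 4, replace = TRUE),
      pressure_change_24h = sample(c(-0.1, 0, 0.1), n_dates * 4,
        replace = TRUE)
    )
  )
  env$timestamp <- as.POSIXct(
    paste(rep(dates, each = 4), sprintf("%02d:00:00", rep(18:21, n_dates))),
    tz = "UTC"
  )
  layout <- lapply(stats::setNames(seq_len(n_dates), as.character(dates)),
    function(i) stats::rbinom(10, 1, 0.3))
  ints <- intervals_from_layout(layout)

  vars <- c("temp_c", "cum_precip_24h", "pressure_change_24h")
  got <- grid_search(ints, env, variables = vars, top_n = Inf)
  cand <- candidate_grid(env, vars)
  want <- brute_force_search(ints, env, cand)

  expect_equal(nrow(got), 6L * 6L * 6L)
  expect_equal(got$rules, want$rules)
  expect_equal(got$n_dates, want$n_dates)
  expect_equal(got$n_pos, want$n_pos)
  expect_equal(got$n_neg, want$n_neg)
  expect_equal(got$ratio, want$ratio)

  # min_dates filtering agrees too.
  got_f <- grid_search(ints, env, variables = vars, min_dates = 4, top_n = Inf)
  want_f <- brute_force_search(ints, env, cand, min_dates = 4)
  expect_equal(got_f$rules, want_f$rules)

  # Returned combos never exceed the unfiltered totals.
  expect_true(all(got$n_pos <= sum(ints$detected)))
  expect_true(all(got$n_dates <= n_dates))

  # One variable, one candidate: grid_search reduces to evaluate_combo.
  one_env <- dplyr::mutate(env, temp_c = 20)
  single <- grid_search(ints, one_env, variables = "temp_c", top_n = Inf)
  gt <- single[grepl(">", single$rules), ]
  direct <- evaluate_combo(ints, one_env,
    rules = threshold_rule("temp_c", "greater_than", 20))
  expect_equal(gt$n_dates, direct$n_dates)
  expect_equal(gt$n_pos, direct$n_pos)
})

test_that("ranking is deterministic", {
  env <- env_from_values(list(temp_c = c(10, 20, 10, 20)),
    start = "2016-02-01 12:00:00")
  env$timestamp <- as.POSIXct(
    paste(as.Date("2016-02-01") + 0:3, "12:00:00"), tz = "UTC"
  )
  ints <- intervals_from_layout(list(
    `2016-02-01` = c(1, 0), `2016-02-02` = c(1, 0),
    `2016-02-03` = c(0, 0), `2016-02-04` = c(1, 1)
  ))
  a <- grid_search(ints, env, variables = "temp_c", top_n = Inf)
  b <- grid_search(ints, env, variables = "temp_c", top_n = Inf)
  expect_identical(a$rules, b$rules)
  expect_identical(a$ratio, b$ratio)
})
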