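#' Candidate thresholds for the environmental grid search
#'
#' For each variable, the candidate thresholds are its unique observed
#' values, optionally decimated to at most `resolution` evenly spaced
#' quantile points for tractability. Each candidate is emitted in both
#' directions (`greater_than` and `less_than`).
#'
#' @param env Hourly environment with derived features.
#' @param variables Character vector of searched variables.
#' @param resolution Maximum candidates per variable (default unlimited).
#' @param moon Moon table, needed only if `moon_illumination` is searched.
#' @return Named list (one per variable) of tibbles with columns
#'   `direction`, `value`, sorted by value within direction.
#' @export
candidate_grid <- function(env, variables, resolution = Inf, moon = NULL) {
  env_aug <- augment_env(env, moon)
  out <- lapply(variables, function(v) {
    if (!v %in% names(env_aug)) {
      stop(sprintf("variable %s is not available in the environmental data",
        dQuote(v)), call. = FALSE)
    }
    vals <- sort(unique(stats::na.omit(env_aug[[v]])))
    if (length(vals) > resolution) {
      vals <- sort(unique(
        sp_quantile(vals, seq(0, 1, length.out = resolution))
      ))
    }
    tidyr::expand_grid(
      direction = c("greater_than", "less_than"), value = vals
    )
  })
  names(out) <- variables
  out
}

#' Evaluate one threshold combination
#'
#' Applies a rule set to the (peak-period-filtered) interval table via
#' [eligible_dates()] and [build_pool()], and reports the surveyable-date
#' count, the detection-positive and -negative interval counts, and their
#' ratio — the objective of the threshold search.
#'
#' @param intervals Peak-period-filtered interval table.
#' @param env Hourly environment with derived features.
#' @param moon Moon table (or `NULL`).
#' @param rules Tibble of threshold rules.
#' @param simultaneous Rule-combination semantics (see [eligible_dates()]).
#' @return One-row tibble: `rules` (canonical description), `n_dates`,
#'   `n_pos`, `n_neg`, `ratio` (`Inf` when positives exist with no
#'   negatives, `NA` when the pool is empty).
#' @export
evaluate_combo <- function(intervals, env, moon = NULL, rules = no_rules(),
                           simultaneous = TRUE) {
  ok <- eligible_dates(env, moon, rules, simultaneous = simultaneous)
  pool <- build_pool(intervals, ok)
  n_pos <- sum(pool$intervals$detected == 1L)
  n_neg <- sum(pool$intervals$detected == 0L)
  tibble::tibble(
    rules = describe_rules(rules),
    n_dates = length(pool$dates),
    n_pos = n_pos, n_neg = n_neg,
    ratio = dplyr::case_when(
      n_pos + n_neg == 0L ~ NA_real_,
      n_neg == 0L ~ Inf,
      TRUE ~ n_pos / n_neg
    )
  )
}

#' Grid search over environmental-threshold combinations
#'
#' Evaluates every combination of one (direction, value) candidate per
#' searched variable and ranks the combinations by the
#' detection:non-detection ratio of the resulting interval pool — the rule
#' sets that best exclude inactive periods from the surveyable season.
#' Combinations leaving fewer than `min_dates` surveyable dates are
#' discarded (a guard against degenerate optima concentrated on a handful of
#' dates). Ties are broken by larger `n_pos`, then larger `n_dates`, then
#' the canonical rule description, so the ranking is a deterministic total
#' order.
#'
#' @inheritParams evaluate_combo
#' @param variables Variables searched (every combination uses one rule per
#'   variable).
#' @param resolution Maximum candidate thresholds per variable
#'   (see [candidate_grid()]).
#' @param min_dates Minimum surveyable dates for a combination to be ranked
#'   (default 0).
#' @param top_n Number of top combinations returned (default 20).
#' @return Tibble of ranked combinations with the columns of
#'   [evaluate_combo()] plus a `rule_set` list-column holding each
#'   combination's rule tibble. Empty (with a warning) if no combination
#'   satisfies `min_dates`.
#' @export
grid_search <- function(intervals, env, moon = NULL, variables,
                        resolution = Inf, min_dates = 0L, top_n = 20L,
                        simultaneous = TRUE) {
  validate_intervals(intervals)
  cands <- candidate_grid(env, variables, resolution = resolution, moon = moon)
  env_aug <- augment_env(env, moon)

  # Per-date bookkeeping over the union of environmental dates, aligned with
  # per-date interval counts so each combination is a few vector ops.
  env_dates <- sort(unique(env_aug$..date))
  date_idx <- match(env_aug$..date, env_dates)
  counts <- intervals |>
    dplyr::group_by(.data$date) |>
    dplyr::summarise(
      pos = sum(.data$detected == 1L), neg = sum(.data$detected == 0L),
      .groups = "drop"
    )
  pos_by_date <- neg_by_date <- rep(0L, length(env_dates))
  has_int <- rep(FALSE, length(env_dates))
  m <- match(counts$date, env_dates)
  keep <- !is.na(m)
  pos_by_date[m[keep]] <- counts$pos[keep]
  neg_by_date[m[keep]] <- counts$neg[keep]
  has_int[m[keep]] <- TRUE

  # Hourly truth vector for every candidate rule, computed once.
  hourly <- lapply(variables, function(v) {
    lapply(seq_len(nrow(cands[[v]])), function(i) {
      eval_rule_hourly(env_aug, v, cands[[v]]$direction[i], cands[[v]]$value[i])
    })
  })
  names(hourly) <- variables

  combos <- expand.grid(
    lapply(variables, function(v) seq_len(nrow(cands[[v]]))),
    KEEP.OUT.ATTRS = FALSE
  )
  names(combos) <- variables

  rows <- purrr::map_dfr(seq_len(nrow(combos)), function(ci) {
    choice <- as.integer(combos[ci, ])
    per_rule <- purrr::map2(variables, choice, function(v, i) hourly[[v]][[i]])
    if (simultaneous) {
      ok_hour <- Reduce(`&`, per_rule)
      elig <- rep(FALSE, length(env_dates))
      elig[date_idx[ok_hour]] <- TRUE
    } else {
      elig <- Reduce(`&`, lapply(per_rule, function(ok) {
        e <- rep(FALSE, length(env_dates))
        e[date_idx[ok]] <- TRUE
        e
      }))
    }
    use <- elig & has_int
    n_pos <- sum(pos_by_date[use])
    n_neg <- sum(neg_by_date[use])
    rule_set <- dplyr::bind_rows(purrr::map2(variables, choice, function(v, i) {
      threshold_rule(v, cands[[v]]$direction[i], cands[[v]]$value[i])
    }))
    tibble::tibble(
      rules = describe_rules(rule_set),
      n_dates = sum(use), n_pos = n_pos, n_neg = n_neg,
      ratio = dplyr::case_when(
        n_pos + n_neg == 0L ~ NA_real_,
        n_neg == 0L ~ Inf,
        TRUE ~ n_pos / n_neg
      ),
      rule_set = list(rule_set)
    )
  })

  rows <- rows[rows$n_dates >= min_dates, , drop = FALSE]
  if (nrow(rows) == 0L) {
    warning("no threshold combination satisfies min_dates", call. = FALSE)
    return(rows)
  }
  ord <- order(-rows$ratio, -rows$n_pos, -rows$n_dates, rows$rules,
    na.last = TRUE
  )
  utils::head(rows[ord, , drop = FALSE], top_n)
}
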