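#' Minimum number of surveys to be confident in absence
#'
#' With per-survey detection probability `p`, the probability that `N`
#' independent surveys all miss a present species is `(1 - p)^N`. The
#' minimum effort for a given confidence in absence is therefore
#' `N_min = ceiling(log(1 - confidence) / log(1 - p))` — e.g. at 95%
#' confidence, the smallest `N` with `(1 - p)^N <= 0.05`. The ceiling makes
#' the returned integer the "at least this many surveys" requirement.
#'
#' @param p Per-survey detection probability, in (0, 1\]; vectorised.
#' @param confidence Required confidence in absence (default 0.95).
#' @return Integer vector of minimum survey counts. `p >= 1` gives 1;
#'   `p <= 0` is an error (absence can never be confirmed).
#' @examples
#' min_surveys(0.063) # 47 five-minute surveys
#' min_surveys(0.5) # 5
#' @export
min_surveys <- function(p, confidence = 0.95) {
  if (any(p <= 0)) {
    stop("p must be positive: with p = 0 absence can never be confirmed",
      call. = FALSE
    )
  }
  if (confidence <= 0 || confidence >= 1) {
    stop("confidence must be in (0, 1)", call. = FALSE)
  }
  n <- rep(1L, length(p))
  below <- p < 1
  n[below] <- as.integer(ceiling(log(1 - confidence) / log(1 - p[below])))
  pmax(n, 1L)
}

# effort_table needs to tolerate a degenerate lower quantile of 0 on sparse
# pools: flag with NA instead of aborting the whole grid.
min_surveys_or_na <- function(p, confidence) {
  out <- rep(NA_integer_, length(p))
  ok <- p > 0
  if (any(!ok)) {
    warning("detection probability of 0 encountered; N reported as NA",
      call. = FALSE
    )
  }
  out[ok] <- min_surveys(p[ok], confidence)
  out
}

#' Survey-effort grid across scenarios and durations
#'
#' For every (scenario pool, survey duration) cell, runs the Monte-Carlo
#' survey simulation, summarises the detection-probability distribution, and
#' converts its mean and 95% band to minimum survey counts. `n_high` pairs
#' with the 2.5% probability quantile (worst case) and `n_low` with the
#' 97.5% quantile.
#'
#' @param pools Named list of `interval_pool`s, one per scenario.
#' @param durations Survey lengths in 5-minute bins (default 1:12, i.e.
#'   5–60 min).
#' @param n_permutations Permutations per cell (default 1000).
#' @param seed Optional integer seed for the whole grid; cells consume one
#'   stream sequentially, so a fixed seed makes the grid reproducible.
#' @param confidence Confidence level for [min_surveys()] (default 0.95).
#' @return A tibble with one row per cell: `scenario`, `duration_min`,
#'   `p_q025`, `p_mean`, `p_q975`, `n_high`, `n_mean`, `n_low`, `n_dates`.
#' @export
effort_table <- function(pools, durations = 1:12, n_permutations = 1000L,
                         seed = NULL, confidence = 0.95) {
  stopifnot(length(pools) > 0L, !is.null(names(pools)))
  if (!is.null(seed)) set.seed(seed)
  grid <- tidyr::expand_grid(
    scenario = names(pools), k = as.integer(durations)
  )
  purrr::pmap_dfr(grid, function(scenario, k) {
    sim <- simulate_surveys(pools[[scenario]], k,
      n_permutations = n_permutations, seed = NULL
    )
    tibble::tibble(
      scenario = scenario,
      duration_min = k * BIN_MINUTES,
      p_q025 = sim$q025, p_mean = sim$mean, p_q975 = sim$q975,
      n_high = min_surveys_or_na(sim$q025, confidence),
      n_mean = min_surveys_or_na(sim$mean, confidence),
      n_low = min_surveys_or_na(sim$q975, confidence),
      n_dates = sim$n_dates
    )
  })
}

#' Plot detection probability and required effort against survey duration
#'
#' Companion figure to [effort_table()]: per scenario, the mean detection
#' probability with its 95% band (bottom facet row) and the corresponding
#' minimum number of surveys (top row), as survey duration increases.
#'
#' @param effort Output of [effort_table()].
#' @return A ggplot object.
#' @export
plot_effort <- function(effort) {
  long <- dplyr::bind_rows(
    dplyr::transmute(effort,
      scenario = .data$scenario, duration_min = .data$duration_min,
      metric = "detection probability",
      mid = .data$p_mean, lo = .data$p_q025, hi = .data$p_q975
    ),
    dplyr::transmute(effort,
      scenario = .data$scenario, duration_min = .data$duration_min,
      metric = "surveys for 95% confidence",
      mid = as.numeric(.data$n_mean), lo = as.numeric(.data$n_low),
      hi = as.numeric(.data$n_high)
    )
  )
  ggplot2::ggplot(long, ggplot2::aes(.data$duration_min, .data$mid)) +
    ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$lo, ymax = .data$hi),
      fill = "grey70", alpha = 0.5
    ) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::facet_grid(
      rows = ggplot2::vars(.data$metric),
      cols = ggplot2::vars(.data$scenario), scales = "free_y"
    ) +
    ggplot2::labs(
      x = "survey duration (min)", y = NULL,
      title = "Detection probability and minimum survey effort"
    ) +
    ggplot2::theme_bw()
}
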