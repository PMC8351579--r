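#' Enumerate valid survey start positions
#'
#' A human survey of `k` consecutive 5-minute intervals can begin wherever
#' `k` gap-free bins exist at one site within one date's pool. For each valid
#' position the window is positive iff any of its `k` bins has a detection.
#'
#' @param pool An `interval_pool`.
#' @param k Survey length in 5-minute bins (1–12 for 5–60 min).
#' @return A tibble with columns `date`, `site_id`, `start_bin` (minutes
#'   since midnight) and `positive` (logical).
#' @export
enumerate_survey_starts <- function(pool, k) {
  stopifnot(inherits(pool, "interval_pool"))
  k <- as.integer(k)
  if (k < 1L) stop("k must be >= 1", call. = FALSE)
  ints <- pool$intervals
  if (nrow(ints) == 0L) {
    return(tibble::tibble(
      date = as.Date(character(0)), site_id = character(0),
      start_bin = integer(0), positive = logical(0)
    ))
  }
  ints |>
    dplyr::arrange(.data$date, .data$site_id, .data$bin_start) |>
    dplyr::group_by(.data$date, .data$site_id) |>
    dplyr::group_modify(function(x, key) {
      bins <- x$bin_start
      det <- x$detected
      run <- cumsum(c(1L, diff(bins) != BIN_MINUTES))
      out <- lapply(split(seq_along(bins), run), function(idx) {
        L <- length(idx)
        if (L < k) {
          return(NULL)
        }
        cs <- c(0L, cumsum(det[idx]))
        n_start <- L - k + 1L
        tibble::tibble(
          start_bin = bins[idx][seq_len(n_start)],
          positive = (cs[seq_len(n_start) + k] - cs[seq_len(n_start)]) > 0L
        )
      })
      res <- dplyr::bind_rows(out)
      if (nrow(res) == 0L) {
        res <- tibble::tibble(start_bin = integer(0), positive = logical(0))
      }
      res
    }) |>
    dplyr::ungroup() |>
    dplyr::select("date", "site_id", "start_bin", "positive")
}

#' Simulate repeated human audio surveys over an interval pool
#'
#' Monte-Carlo resampling of survey outcomes: within one permutation, one
#' survey of `k` consecutive 5-minute bins is drawn uniformly at random from
#' the valid start positions of every pool date (one survey per date, so no
#' date is sampled twice within a permutation), and the detection-probability
#' estimate is the fraction of dates whose survey window contained a
#' detection. Repeating over `n_permutations` seeded permutations yields the
#' distribution summarised by its mean and 2.5/97.5% quantiles.
#'
#' When both sites have valid positions on a date, the uniform draw is over
#' the union of positions, so a site is chosen with probability proportional
#' to its number of positions (detection data are pooled across sites).
#' Dates with no valid `k`-bin position are dropped from that simulation
#' with a warning and counted in `n_dropped_dates`.
#'
#' With `contiguous = FALSE` a survey is instead `k` distinct 5-minute bins
#' drawn without replacement from the date's pool (any site, any time); the
#' outcome is then drawn from the equivalent hypergeometric law.
#'
#' @param pool An `interval_pool`.
#' @param k Survey length in 5-minute bins.
#' @param n_permutations Number of permutations (default 1000).
#' @param seed Optional integer seed; identical seeds give bit-identical
#'   estimate vectors.
#' @param contiguous Survey mechanism (see above; default contiguous).
#' @return A `detection_prob_dist`: list with `estimates` (length
#'   `n_permutations`, each a multiple of `1/n_dates`), `mean`, `q025`,
#'   `q975`, `n_dates`, `k`, `n_permutations`, `n_dropped_dates`.
#' @export
simulate_surveys <- function(pool, k, n_permutations = 1000L, seed = NULL,
                             contiguous = TRUE) {
  stopifnot(inherits(pool, "interval_pool"))
  if (pool$empty) stop("cannot simulate surveys over an empty pool", call. = FALSE)
  n_permutations <- as.integer(n_permutations)
  stopifnot(n_permutations >= 1L)
  if (!is.null(seed)) set.seed(seed)

  if (contiguous) {
    starts <- enumerate_survey_starts(pool, k)
    per_date <- split(starts$positive, starts$date)
    n_dropped <- length(pool$dates) - length(per_date)
  } else {
    per_date <- lapply(split(pool$intervals$detected, pool$intervals$date),
      function(det) if (length(det) >= k) det else NULL)
    per_date <- per_date[!vapply(per_date, is.null, TRUE)]
    n_dropped <- length(pool$dates) - length(per_date)
  }
  if (length(per_date) == 0L) {
    stop(sprintf("no date in the pool can host a %d-bin survey", k),
      call. = FALSE
    )
  }
  if (n_dropped > 0L) {
    warning(sprintf(
      "%d date(s) lack a valid %d-bin survey position and were dropped",
      n_dropped, k
    ), call. = FALSE)
  }

  positives <- integer(n_permutations)
  if (contiguous) {
    for (pos in per_date) {
      idx <- sample.int(length(pos), n_permutations, replace = TRUE)
      positives <- positives + pos[idx]
    }
  } else {
    for (det in per_date) {
      m <- length(det)
      n_neg <- sum(det == 0L)
      p_pos <- 1 - exp(lchoose(n_neg, k) - lchoose(m, k))
      positives <- positives + stats::rbinom(n_permutations, 1L, p_pos)
    }
  }
  estimates <- positives / length(per_date)
  q <- sp_quantile(estimates, c(0.025, 0.975))
  structure(
    list(
      estimates = estimates, mean = mean(estimates),
      q025 = q[1], q975 = q[2],
      n_dates = length(per_date), k = k,
      n_permutations = n_permutations, n_dropped_dates = n_dropped
    ),
    class = "detection_prob_dist"
  )
}

#' @export
print.detection_prob_dist <- function(x, ...) {
  cat(sprintf(
    "<detection_prob_dist> %d-min surveys on %d dates, %d permutations\n  p = %.3f (95%% band %.3f-%.3f)\n",
    x$k * BIN_MINUTES, x$n_dates, x$n_permutations, x$mean, x$q025, x$q975
  ))
  invisible(x)
}

#' Exact expected detection probability of a random survey
#'
#' Closed form for the quantity [simulate_surveys()] estimates under the
#' contiguous mechanism: the mean over pool dates of the fraction of valid
#' `k`-bin start positions whose window contains a detection. Used as the
#' independent oracle for the simulator.
#'
#' @inheritParams simulate_surveys
#' @return A single probability.
#' @export
analytic_mean <- function(pool, k) {
  stopifnot(inherits(pool, "interval_pool"))
  if (pool$empty) stop("cannot evaluate an empty pool", call. = FALSE)
  starts <- enumerate_survey_starts(pool, k)
  if (nrow(starts) == 0L) {
    stop(sprintf("no date in the pool can host a %d-bin survey", k),
      call. = FALSE
    )
  }
  per_date <- vapply(split(starts$positive, starts$date), mean, 1)
  mean(per_date)
}
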