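resolve_scenario <- function(x) {
  if (inherits(x, "survey_scenario")) {
    return(x)
  }
  if (is.character(x) && length(x) == 1L) {
    return(switch(x,
      random = scenario_random(),
      usfws = scenario_usfws(),
      optimized = scenario_optimized(),
      stop(sprintf("unknown scenario preset %s", dQuote(x)), call. = FALSE)
    ))
  }
  if (is.list(x)) {
    rules <- no_rules()
    if (!is.null(x$rules)) {
      rules <- dplyr::bind_rows(lapply(x$rules, function(r) {
        threshold_rule(r$variable, r$direction, r$value)
      }))
    }
    return(scenario(
      name = x$name %||% "custom",
      months = x$months %||% 2:4,
      night_start = x$night_start %||% "18:00",
      morning_end = x$morning_end %||% "06:00",
      rules = rules,
      simultaneous = x$simultaneous %||% TRUE
    ))
  }
  stop("cannot interpret scenario specification", call. = FALSE)
}

#' Run the full survey-power pipeline
#'
#' End-to-end orchestration: obtain inputs (from files or the synthetic
#' generator), derive environmental features, summarise conditions on
#' detection-positive dates, build the scenario pools, compute the
#' scenario-by-duration effort grid, and optionally run the environmental
#' threshold search. All outputs are written as CSV into `out_dir` along
#' with a JSON provenance manifest (config hash, seed, per-stage row counts,
#' collected warnings). Reruns with the same config are deterministic.
#'
#' @param config Configuration as a nested list, or the path to a YAML file
#'   with the same structure. Recognised keys:
#' \describe{
#'   \item{`seed`}{integer root seed (required).}
#'   \item{`inputs`}{list with file paths `intervals`, `env`, `moon` — or
#'     omitted to simulate inputs.}
#'   \item{`synth`}{list of [synthetic_params()] overrides (used when
#'     `inputs` is absent).}
#'   \item{`scenarios`}{vector of preset names (`"random"`, `"usfws"`,
#'     `"optimized"`) and/or custom scenario lists.}
#'   \item{`durations_min`}{survey durations in minutes (default 5–60 by 5).}
#'   \item{`permutations`}{permutations per cell (default 1000).}
#'   \item{`threshold_search`}{optional list with `variables` and optionally
#'     `resolution`, `min_dates`, `top_n`.}
#' }
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with `effort`, `conditions`, `search` (or
#'   `NULL`), `pools` and the `manifest`.
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  if (is.null(config$seed)) stop("config must provide a seed", call. = FALSE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  warnings_log <- character(0)
  run_stage <- function(name, expr) {
    withCallingHandlers(
      tryCatch(expr, error = function(e) {
        stop(sprintf("stage '%s': %s", name, conditionMessage(e)),
          call. = FALSE
        )
      }),
      warning = function(w) {
        warnings_log <<- c(warnings_log,
          sprintf("[%s] %s", name, conditionMessage(w)))
        invokeRestart("muffleWarning")
      }
    )
  }

  inputs <- run_stage("inputs", {
    if (!is.null(config$inputs)) {
      ii <- config$inputs
      if (is.null(ii$intervals) || is.null(ii$env)) {
        stop("inputs must name intervals and env files")
      }
      list(
        intervals = read_interval_table(ii$intervals),
        env = read_hourly_environment(ii$env),
        moon = if (!is.null(ii$moon)) read_moon(ii$moon) else NULL
      )
    } else if (!is.null(config$synth) || isTRUE(config$use_synth_defaults)) {
      params <- do.call(
        synthetic_params,
        c(config$synth %||% list(), list(seed = as.integer(config$seed)))
      )
      generate_dataset(params)
    } else {
      stop("config must provide either inputs files or synth parameters")
    }
  })

  env <- run_stage("derive_features", derive_env_features(inputs$env))

  conditions <- run_stage("detection_conditions", {
    summarize_detection_conditions(inputs$intervals, env, inputs$moon)
  })

  scns <- lapply(config$scenarios %||% list("random", "usfws", "optimized"),
    resolve_scenario)
  pools <- run_stage("scenario_pools", {
    out <- lapply(scns, function(s) {
      scenario_pool(inputs$intervals, env, inputs$moon, s)
    })
    names(out) <- vapply(scns, function(s) s$name, "")
    out
  })

  durations_min <- config$durations_min %||% seq(5, 60, by = 5)
  if (any(durations_min %% 5 != 0)) {
    stop("stage 'effort': durations_min must be multiples of 5", call. = FALSE)
  }
  effort <- run_stage("effort", {
    effort_table(pools,
      durations = as.integer(durations_min) %/% 5L,
      n_permutations = as.integer(config$permutations %||% 1000L),
      seed = as.integer(config$seed) + 1L
    )
  })

  search <- NULL
  if (!is.null(config$threshold_search)) {
    ts_cfg <- config$threshold_search
    search <- run_stage("threshold_search", {
      grid_search(
        peak_period_filter(inputs$intervals), env, inputs$moon,
        variables = ts_cfg$variables,
        resolution = ts_cfg$resolution %||% Inf,
        min_dates = ts_cfg$min_dates %||% 0L,
        top_n = ts_cfg$top_n %||% 20L
      )
    })
  }

  run_stage("write_outputs", {
    write_interval_table(inputs$intervals, file.path(out_dir, "intervals.csv"))
    readr::write_csv(conditions, file.path(out_dir, "detection_conditions.csv"),
      progress = FALSE)
    readr::write_csv(effort, file.path(out_dir, "effort.csv"),
      progress = FALSE)
    if (!is.null(search)) {
      readr::write_csv(dplyr::select(search, -"rule_set"),
        file.path(out_dir, "threshold_search.csv"), progress = FALSE)
    }
  })

  manifest <- list(
    config_hash = rlang::hash(config),
    seed = as.integer(config$seed),
    stages = list(
      intervals_rows = nrow(inputs$intervals),
      env_rows = nrow(env),
      pool_sizes = lapply(pools, function(p) {
        list(intervals = nrow(p$intervals), dates = length(p$dates))
      }),
      effort_cells = nrow(effort),
      search_rows = if (is.null(search)) 0L else nrow(search)
    ),
    warnings = warnings_log
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
    auto_unbox = TRUE, pretty = TRUE
  )

  invisible(list(
    effort = effort, conditions = conditions, search = search,
    pools = pools, manifest = manifest
  ))
}
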