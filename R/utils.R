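# Internal helpers shared across modules.

BIN_MINUTES <- 5L
BINS_PER_DAY <- 288L

# All quantiles in the package flow through this single method so that the
# interpolation rule is configurable globally (default: type 7, linear
# interpolation between order statistics).
sp_quantile <- function(x, probs) {
  stats::quantile(x, probs,
    type = getOption("surveypower.quantile_type", 7L),
    names = FALSE, na.rm = FALSE
  )
}

# bin_start is carried internally as integer minutes since midnight on the
# 5-minute grid; "HH:MM" at the file boundary.
format_bin <- function(bin) {
  sprintf("%02d:%02d", bin %/% 60L, bin %% 60L)
}

parse_bin <- function(x) {
  ok <- grepl("^\\d{1,2}:\\d{2}$", x)
  if (!all(ok)) {
    stop("unparseable bin_start value(s): ",
      paste(utils::head(x[!ok], 3L), collapse = ", "),
      call. = FALSE
    )
  }
  h <- as.integer(sub(":.*", "", x))
  m <- as.integer(sub(".*:", "", x))
  bin <- h * 60L + m
  if (any(h > 23L | m > 59L)) {
    stop("bin_start outside the 24-h clock", call. = FALSE)
  }
  if (any(bin %% BIN_MINUTES != 0L)) {
    stop("bin_start not aligned to the 5-minute grid", call. = FALSE)
  }
  bin
}

require_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0L) {
    stop(sprintf(
      "%s is missing required column(s): %s",
      what, paste(missing, collapse = ", ")
    ), call. = FALSE)
  }
  invisible(df)
}

# Canonical one-line description of a rule set, e.g.
# "temp_c > 16 & cum_precip_24h > 0". Used for display and tie-breaking.
describe_rules <- function(rules) {
  if (nrow(rules) == 0L) {
    return("(no rules)")
  }
  op <- ifelse(rules$direction == "greater_than", ">", "<")
  paste(sprintf("%s %s %g", rules$variable, op, rules$value), collapse = " & ")
}
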