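# Shared conventions: quantiles use linear interpolation between order
# statistics (stats::quantile type 7); timestamps are naive local camera time
# (no DST); day of year is 1-based and fractional for sub-daily samples.

# Linear-interpolation quantile, the package-wide convention.
pheno_quantile <- function(x, probs) {
  stats::quantile(x, probs = probs, type = 7, names = FALSE, na.rm = TRUE)
}

#' Fractional day of year
#'
#' Converts timestamps to 1-based fractional day of year in naive local time
#' (midnight on 1 January is day 1.0; noon is day 1.5).
#'
#' @param time A `POSIXct` vector.
#' @return Numeric vector of fractional days of year.
#' @export
fractional_doy <- function(time) {
  lt <- as.POSIXlt(time, tz = attr(time, "tzone") %||% "UTC")
  lt$yday + 1 + (lt$hour + lt$min / 60 + lt$sec / 3600) / 24
}

# POSIXct from fractional doy in a fixed (non-leap by default) year.
time_from_doy <- function(doy, year = 2015L) {
  origin <- as.POSIXct(sprintf("%d-01-01 00:00:00", year), tz = "UTC")
  origin + (doy - 1) * 86400
}

# --- filter bookkeeping ------------------------------------------------------

filters_applied <- function(series) attr(series, "pheno_filters") %||% character()

# Stamp a filter application and accumulate its report. Order is enforced by
# the individual filters via assert_filter_order().
mark_filter <- function(series, name, report) {
  attr(series, "pheno_filters") <- c(filters_applied(series), name)
  reports <- attr(series, "filter_reports") %||% list()
  reports[[name]] <- report
  attr(series, "filter_reports") <- reports
  series
}

# The chain order is night/snow -> spline -> max; a filter refuses to run
# after a later stage unless explicitly overridden.
assert_filter_order <- function(series, stage, override = FALSE) {
  if (override) return(invisible(TRUE))
  applied <- filters_applied(series)
  later <- switch(stage,
    night = c("spline", "max"),
    spline = "max",
    max = character()
  )
  bad <- intersect(applied, later)
  if (length(bad) > 0) {
    abort(sprintf(
      "filter order violated: '%s' cannot run after '%s' (chain is night -> spline -> max); use override = TRUE to force",
      stage, paste(bad, collapse = ", ")
    ))
  }
  invisible(TRUE)
}

#' Retrieve filter reports attached to a series
#'
#' Each filtering step attaches a report (counts in/removed, thresholds used).
#'
#' @param series A chromatic series tibble that has passed through one or more
#'   filters.
#' @return A named list of filter reports (possibly empty).
#' @export
filter_report <- function(series) {
  attr(series, "filter_reports") %||% list()
}

# Carry pheno attributes through dplyr verbs that strip them.
restore_pheno_attrs <- function(new, old) {
  attr(new, "pheno_filters") <- attr(old, "pheno_filters")
  attr(new, "filter_reports") <- attr(old, "filter_reports")
  attr(new, "aggregation") <- attr(old, "aggregation")
  new
}
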