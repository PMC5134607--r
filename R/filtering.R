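# Sub-daily GCC cleaning. The chain, in the order it must run:
#   (snow/)night filter -> spline outlier filter -> 3-day moving-window
#   90th-percentile ("max") filter, yielding a daily series.

#' Filter configuration
#'
#' Bundles the tunable parameters of the filter chain.
#'
#' @param night_threshold Fixed lower GCC bound for the night filter
#'   (default 0.2): samples strictly below it are dark/ill-exposed frames.
#' @param max_filter_window Moving-window width in days for the max filter
#'   (odd; default 3).
#' @param max_filter_percentile Window percentile retained by the max filter
#'   (default 90).
#' @param snow_filter_enabled Run the automated CDF-breakpoint snow filter
#'   (default `TRUE`).
#' @param breakpoint_min_segment_fraction Smallest admissible segment in the
#'   breakpoint search, as a fraction of samples (default 0.05, so snow
#'   fractions down to ~5% remain representable).
#' @param snow_floor Keep the data-driven snow threshold at or above the
#'   fixed night threshold (default `TRUE`): the snow filter augments, never
#'   relaxes, the night filter.
#' @param spline_outlier_sd Downward-residual rejection multiple for the
#'   spline filter (default 2).
#' @param spline_iterations Refit-and-reject passes of the spline filter
#'   (default 2).
#' @param spline_spar_mult Multiplier applied to the GCV-chosen smoothing
#'   parameter of the outlier spline (default 1).
#' @return A `filter_config` list.
#' @export
filter_config <- function(night_threshold = 0.2,
                          max_filter_window = 3L,
                          max_filter_percentile = 90,
                          snow_filter_enabled = TRUE,
                          breakpoint_min_segment_fraction = 0.05,
                          snow_floor = TRUE,
                          spline_outlier_sd = 2,
                          spline_iterations = 2L,
                          spline_spar_mult = 1) {
  stopifnot(night_threshold > 0, night_threshold < 1,
            max_filter_window >= 1, max_filter_window %% 2 == 1,
            max_filter_percentile > 0, max_filter_percentile < 100,
            breakpoint_min_segment_fraction > 0,
            breakpoint_min_segment_fraction < 0.5,
            spline_outlier_sd > 0, spline_iterations >= 1)
  structure(list(
    night_threshold = night_threshold,
    max_filter_window = as.integer(max_filter_window),
    max_filter_percentile = max_filter_percentile,
    snow_filter_enabled = isTRUE(snow_filter_enabled),
    breakpoint_min_segment_fraction = breakpoint_min_segment_fraction,
    snow_floor = isTRUE(snow_floor),
    spline_outlier_sd = spline_outlier_sd,
    spline_iterations = as.integer(spline_iterations),
    spline_spar_mult = spline_spar_mult
  ), class = "filter_config")
}

new_filter_report <- function(n_input, n_removed, stage, threshold = NULL) {
  list(stage = stage, n_input = n_input, n_removed = n_removed,
       n_retained = n_input - n_removed, threshold = threshold)
}

#' Fixed night filter
#'
#' Removes sub-daily samples with GCC strictly below a threshold (dark,
#' foggy or badly white-balanced frames). Samples at exactly the threshold
#' are retained.
#'
#' @param series Sub-daily chromatic series tibble with a `gcc` column.
#' @param threshold GCC lower bound (default 0.2).
#' @param override Allow running out of chain order.
#' @return The filtered series (report retrievable via [filter_report()]).
#' @export
night_filter <- function(series, threshold = 0.2, override = FALSE) {
  assert_filter_order(series, "night", override)
  keep <- series$gcc >= threshold
  out <- restore_pheno_attrs(series[keep, , drop = FALSE], series)
  if (!any(keep)) warn("night filter removed every sample: empty series")
  mark_filter(out, "night",
              new_filter_report(nrow(series), sum(!keep), "night", threshold))
}

# Closed-form OLS line fit on sorted (x, y) index range [i, j] from prefix
# sums; used by the exhaustive segmented-regression search. Returns RSS
# (`$rss`) and slope (`$slope`) evaluators.
segment_ols_fun <- function(x, y) {
  cx <- c(0, cumsum(x)); cy <- c(0, cumsum(y))
  cxx <- c(0, cumsum(x^2)); cyy <- c(0, cumsum(y^2)); cxy <- c(0, cumsum(x * y))
  moments <- function(i, j) {
    n <- j - i + 1
    sx <- cx[j + 1] - cx[i]; sy <- cy[j + 1] - cy[i]
    list(n = n,
         sxx = cxx[j + 1] - cxx[i] - sx^2 / n,
         syy = cyy[j + 1] - cyy[i] - sy^2 / n,
         sxy = cxy[j + 1] - cxy[i] - sx * sy / n)
  }
  list(
    rss = function(i, j) {
      m <- moments(i, j)
      pmax(ifelse(m$sxx > 1e-12, m$syy - m$sxy^2 / m$sxx, m$syy), 0)
    },
    slope = function(i, j) {
      m <- moments(i, j)
      ifelse(m$sxx > 1e-12, m$sxy / m$sxx, NA_real_)
    }
  )
}

#' Data-driven snow/night GCC threshold from the CDF of GCC
#'
#' Ephemeral snow produces a cluster of unreasonably low GCC values that
#' bends the otherwise near-linear lower range of the empirical cumulative
#' distribution of GCC. The sorted GCC values are regressed on their
#' cumulative fraction and a piecewise-linear (segmented) regression with up
#' to 3 segments is fit by exhaustive least squares; BIC chooses the number
#' of segments, and the first breakpoint is accepted only when the first
#' segment is materially steeper than the second (`slope_ratio_min`, default
#' 2) -- the signature of a sparse low-GCC contamination cluster diverging
#' from the lower range, as opposed to the flat-to-steep bend a clean
#' seasonal distribution shows. The threshold is the GCC value at the
#' accepted breakpoint: the midpoint of the two sorted values straddling it.
#'
#' @param series Sub-daily series tibble with `gcc`, or a numeric GCC vector.
#' @param min_segment_fraction Minimum segment length as a fraction of the
#'   sample (default 0.05); tail breaks are otherwise controlled by the BIC
#'   penalty and the slope-ratio rule.
#' @param max_segments Maximum number of linear segments tried (default 3).
#' @param slope_ratio_min Minimum ratio of first- to second-segment slope
#'   for a breakpoint to count as snow contamination (default 2).
#' @return The GCC threshold, or `NA_real_` when fewer than 20 samples are
#'   available or no statistically supported snow breakpoint exists.
#' @export
snow_threshold_from_cdf <- function(series, min_segment_fraction = 0.05,
                                    max_segments = 3L, slope_ratio_min = 2) {
  g <- if (is.numeric(series)) series else series$gcc
  g <- g[!is.na(g)]
  n <- length(g)
  if (n < 20) return(NA_real_)
  y <- sort(g)
  x <- seq_len(n) / n
  ols <- segment_ols_fun(x, y)
  rss <- ols$rss
  minseg <- max(4L, ceiling(min_segment_fraction * n))
  p_per_seg <- 3  # slope + intercept + breakpoint
  bic <- function(total_rss, m) {
    n * log(max(total_rss, 1e-12) / n) + (p_per_seg * m - 1) * log(n)
  }
  if (n < 2 * minseg) return(NA_real_)
  bic_best_m <- 1
  bic_min <- bic(rss(1, n), 1)
  ks <- minseg:(n - minseg)               # last index of segment 1
  tot2 <- rss(1, ks) + rss(ks + 1, n)
  k <- ks[which.min(tot2)]                # two-segment breakpoint
  if (max_segments >= 2) {
    b2 <- bic(min(tot2), 2)
    if (b2 < bic_min) { bic_min <- b2; bic_best_m <- 2 }
  }
  if (max_segments >= 3 && n >= 3 * minseg) {
    best3 <- Inf
    for (k1 in minseg:(n - 2 * minseg)) {
      k2 <- (k1 + minseg):(n - minseg)
      tot3 <- rss(1, k1) + rss(k1 + 1, k2) + rss(k2 + 1, n)
      best3 <- min(best3, min(tot3))
    }
    b3 <- bic(best3, 3)
    if (b3 < bic_min) { bic_min <- b3; bic_best_m <- 3 }
  }
  if (bic_best_m == 1) return(NA_real_)
  # threshold and contamination signature always from the two-segment fit:
  # the break between the first and the second regression
  s1 <- ols$slope(1, k)
  s2 <- ols$slope(k + 1, n)
  if (!is.finite(s1) || !is.finite(s2) || s2 <= 0 ||
      s1 / s2 < slope_ratio_min) {
    return(NA_real_)
  }
  (y[k] + y[k + 1]) / 2
}

#' Automated variable snow/night filter
#'
#' Applies the night filter at the larger of the fixed night threshold and
#' the data-driven CDF-breakpoint threshold of
#' [snow_threshold_from_cdf()]. When no breakpoint is supported it reduces
#' exactly to the fixed night filter. Applied per ROI when a `roi` column
#' with several levels is present.
#'
#' @param series Sub-daily chromatic series tibble.
#' @param config A [filter_config()].
#' @param override Allow running out of chain order.
#' @return The filtered series; the report records the threshold used and
#'   `snow_threshold` (the breakpoint value, `NA` if none).
#' @export
snow_night_filter <- function(series, config = filter_config(),
                              override = FALSE) {
  assert_filter_order(series, "night", override)
  if ("roi" %in% names(series) && dplyr::n_distinct(series$roi) > 1) {
    pieces <- split(series, series$roi)
    out <- dplyr::bind_rows(purrr::map(pieces, snow_night_filter,
                                       config = config, override = TRUE))
    return(restore_pheno_attrs(out, series))
  }
  bp <- if (config$snow_filter_enabled) {
    snow_threshold_from_cdf(series, config$breakpoint_min_segment_fraction)
  } else NA_real_
  thr <- if (is.na(bp)) {
    config$night_threshold
  } else if (config$snow_floor) {
    max(bp, config$night_threshold)
  } else bp
  keep <- series$gcc >= thr
  if (!any(keep)) warn("snow/night filter removed every sample: empty series")
  out <- restore_pheno_attrs(series[keep, , drop = FALSE], series)
  rep <- new_filter_report(nrow(series), sum(!keep), "snow_night", thr)
  rep$snow_threshold <- bp
  mark_filter(out, "night", rep)
}

#' Spline-based outlier filter
#'
#' Iteratively fits a smoothing spline (GCV-chosen smoothness) to GCC over
#' time and removes samples whose residual is below
#' `-spline_outlier_sd * sd(residuals)`. Only downward outliers are removed:
#' in camera greenness series the artifacts (shadow, weather, exposure) are
#' drops, not spikes.
#'
#' @inheritParams snow_night_filter
#' @return The filtered series with an attached report.
#' @export
spline_filter <- function(series, config = filter_config(), override = FALSE) {
  assert_filter_order(series, "spline", override)
  n0 <- nrow(series)
  if (n0 < 10 || dplyr::n_distinct(floor(series$doy)) < 5) {
    warn("too few samples for the spline filter; returning input unchanged")
    return(mark_filter(series, "spline",
                       new_filter_report(n0, 0L, "spline")))
  }
  keep <- rep(TRUE, n0)
  for (it in seq_len(config$spline_iterations)) {
    x <- series$doy[keep]; y <- series$gcc[keep]
    fit <- tryCatch({
      f0 <- smooth.spline(x, y, cv = FALSE)
      if (config$spline_spar_mult != 1) {
        smooth.spline(x, y, spar = min(1.5, f0$spar * config$spline_spar_mult))
      } else f0
    }, error = function(e) NULL)
    if (is.null(fit)) break
    res <- y - predict(fit, x)$y
    s <- sd(res)
    if (!is.finite(s) || s < 1e-8) break  # spline is (near-)exact: nothing to reject
    drop <- res < -config$spline_outlier_sd * s
    if (!any(drop)) break
    keep[which(keep)[drop]] <- FALSE
  }
  out <- restore_pheno_attrs(series[keep, , drop = FALSE], series)
  mark_filter(out, "spline",
              new_filter_report(n0, sum(!keep), "spline"))
}

#' Moving-window percentile ("max") filter to daily resolution
#'
#' For every calendar day with at least one retained sub-daily sample in the
#' centred window (day - 1 .. day + 1 for a 3-day window), outputs the window
#' percentile (linear-interpolation quantile) of GCC. Days whose window holds
#' no samples are absent from the output.
#'
#' @param series Sub-daily (or daily) chromatic series tibble with `doy` and
#'   `gcc`.
#' @param window_days Window width in days (odd; default 3).
#' @param percentile Window percentile (default 90).
#' @return A daily tibble with `doy` (integer day), `gcc`, and `n_obs`
#'   (samples in the window); grouped per `roi` when present. Attribute
#'   `aggregation` is `"daily"`.
#' @export
max_filter <- function(series, window_days = 3L, percentile = 90) {
  stopifnot(window_days >= 1, window_days %% 2 == 1)
  if (nrow(series) == 0) {
    out <- tibble::tibble(doy = integer(), gcc = numeric(), n_obs = integer())
    attr(out, "aggregation") <- "daily"
    return(out)
  }
  half <- (window_days - 1) / 2
  one <- function(df) {
    day <- floor(df$doy)
    days <- seq(min(day), max(day))
    rows <- purrr::map(days, function(d) {
      in_win <- day >= d - half & day <= d + half
      if (!any(in_win)) return(NULL)
      tibble::tibble(doy = d,
                     gcc = pheno_quantile(df$gcc[in_win], percentile / 100),
                     n_obs = sum(in_win))
    })
    dplyr::bind_rows(rows)
  }
  out <- if ("roi" %in% names(series)) {
    dplyr::bind_rows(purrr::map(split(series, series$roi), function(df) {
      dplyr::mutate(one(df), roi = df$roi[1], .before = 1)
    }))
  } else one(series)
  out <- restore_pheno_attrs(out, series)
  attr(out, "aggregation") <- "daily"
  mark_filter(out, "max",
              new_filter_report(nrow(series), NA_integer_, "max"))
}

#' Centred 3-day moving average for daily environmental series
#'
#' Smooths a daily series with a centred mean over the available values in
#' the 3-day window; edge days and days adjacent to gaps use the values that
#' exist.
#'
#' @param data A data frame with a day column and a value column, or a
#'   numeric vector of consecutive daily values.
#' @param value Column name of the value (default `"value"`).
#' @param day Column name of the day index/date (default `"date"`).
#' @return The input with an added `smoothed` column (or a numeric vector if
#'   the input was a vector).
#' @export
moving_average_3day <- function(data, value = "value", day = "date") {
  if (is.numeric(data)) {
    d <- seq_along(data); v <- data
  } else {
    d <- as.numeric(data[[day]]); v <- data[[value]]
  }
  sm <- purrr::map_dbl(seq_along(d), function(i) {
    in_win <- abs(d - d[i]) <= 1 & !is.na(v)
    if (!any(in_win)) return(NA_real_)
    mean(v[in_win])
  })
  if (is.numeric(data)) return(sm)
  data$smoothed <- sm
  data
}

#' Full filter chain: snow/night, spline, max
#'
#' Runs the three filters in the required order and returns the daily series.
#'
#' @inheritParams snow_night_filter
#' @return Daily chromatic series; all three stage reports attached
#'   (see [filter_report()]).
#' @export
filter_chain <- function(series, config = filter_config()) {
  series |>
    snow_night_filter(config) |>
    spline_filter(config) |>
    max_filter(config$max_filter_window, config$max_filter_percentile)
}

#' Serialize filter reports as JSON
#'
#' @param series A filtered series (or a list of reports from
#'   [filter_report()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_filter_report <- function(series, path) {
  reports <- if (is.data.frame(series)) filter_report(series) else series
  jsonlite::write_json(reports, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}
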