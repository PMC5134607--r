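# Per-pixel ("spatiotemporal") phenology: smoothing-spline fits per pixel,
# phenophase maps, histogram-window vegetation/interspace separation, GCC
# range maps, and a mean-changepoint split of the interspace class.
#
# Splines are used instead of the double logistic because single-pixel
# trajectories are too noisy for the 9-parameter fit; phenophases come from
# the same Gu line-intersection geometry applied to the spline. No
# uncertainty ensemble is computed per pixel.

#' Per-pixel daily trajectories from rendered frames
#'
#' Reads every frame of an image index, extracts per-pixel GCC inside the
#' ROI, and aggregates to daily means per pixel.
#'
#' @param images Tibble from [load_image_series()].
#' @param roi A `pheno_roi`.
#' @return A `pixel_trajectories` long tibble (`row`, `col`, `doy`, `gcc`).
#' @export
pixel_trajectories <- function(images, roi) {
  per_frame <- purrr::map2(images$path, images$doy, function(path, doy) {
    fr <- tryCatch(read_frame(path), error = function(e) NULL)
    if (is.null(fr)) return(NULL)
    px <- extract_chromatic(fr, roi, scope = "per-pixel")
    px$doy <- floor(doy)
    px[, c("row", "col", "doy", "gcc")]
  })
  long <- dplyr::bind_rows(per_frame)
  out <- long |>
    dplyr::group_by(.data$row, .data$col, .data$doy) |>
    dplyr::summarise(gcc = mean(.data$gcc), .groups = "drop")
  structure(out, dims = dim(roi$mask),
            class = c("pixel_trajectories", class(out)))
}

# Spline degrees of freedom: ~ n/8 bounded to [6, 20].
spline_df <- function(n) min(20, max(6, round(n / 8)))

fit_pixel_spline <- function(doy, gcc, plateau = TRUE, grid_step = 0.25) {
  fit <- tryCatch(
    smooth.spline(doy, gcc, df = spline_df(length(doy))),
    error = function(e) NULL)
  if (is.null(fit)) return(NULL)
  tg <- seq(min(doy), max(doy), by = grid_step)
  yg <- predict(fit, tg)$y
  dg <- predict(fit, tg, deriv = 1)$y
  ph <- phases_from_grid(tg, yg, dg, plateau = plateau)
  ph$resid_sd <- sd(gcc - predict(fit, doy)$y)
  ph
}

#' Fit per-pixel splines and extract a phenophase map
#'
#' For every pixel with at least 20 daily values, fits a cubic smoothing
#' spline to its daily GCC and applies the Gu line-intersection geometry to
#' the spline, producing per-pixel UD/SD/DD/RD, GSL and GCC range. Pixels
#' whose fit fails, that show no seasonal cycle, or whose seasonal amplitude
#' is indistinguishable from their own fit noise (amplitude below `min_snr`
#' times the spline residual SD -- flat-noise pixels) are marked `excluded`;
#' failures never abort the map. GSL at this stage is raw RD - UD and can be
#' negative for noisy weak-signal pixels; [filter_histogram()] removes those.
#'
#' @param trajectories A `pixel_trajectories` tibble.
#' @param plateau Apply the plateau-line DD adjustment (default `TRUE`).
#' @param min_snr Minimum ratio of smoothed seasonal amplitude to spline
#'   residual SD for a pixel to count as carrying a signal (default 1.5,
#'   a deliberately conservative gate).
#' @return A `pheno_map` tibble: `row`, `col`, `ud`, `sd`, `dd`, `rd`,
#'   `gsl`, `range_gcc`, `class` (`"unclassified"` or `"excluded"`).
#' @export
fit_per_pixel <- function(trajectories, plateau = TRUE, min_snr = 1.5) {
  pixels <- dplyr::group_split(trajectories, .data$row, .data$col)
  rows <- purrr::map(pixels, function(px) {
    base <- tibble::tibble(row = px$row[1], col = px$col[1],
                           ud = NA_real_, sd = NA_real_, dd = NA_real_,
                           rd = NA_real_, gsl = NA_real_,
                           range_gcc = NA_real_, class = "excluded")
    ok <- !is.na(px$gcc)
    if (sum(ok) < 20) return(base)
    ph <- fit_pixel_spline(px$doy[ok], px$gcc[ok], plateau = plateau)
    if (is.null(ph)) return(base)
    base$range_gcc <- ph$range_gcc
    if (!ph$flag %in% c("ok", "inverted-cycle") ||
        !is.finite(ph$UD) || !is.finite(ph$RD)) return(base)
    if (is.finite(ph$resid_sd) && ph$range_gcc < min_snr * ph$resid_sd) {
      return(base)  # no resolvable seasonal signal
    }
    base$ud <- ph$UD; base$sd <- ph$SD; base$dd <- ph$DD; base$rd <- ph$RD
    base$gsl <- ph$RD - ph$UD
    base$class <- "unclassified"
    base
  })
  out <- dplyr::bind_rows(rows)
  structure(out, dims = attr(trajectories, "dims"),
            class_map = attr(trajectories, "class_map"),
            class = c("pheno_map", class(out)))
}

#' Histogram acceptance window for UD and RD
#'
#' Day-of-year bounds outside which a pixel's UD or RD is judged spurious
#' (outside the predominant bell of the scene's phenophase histograms).
#' Defaults correspond to a temperate-zone growing season: UD in (50, 170),
#' RD in (170, 330).
#'
#' @param ud_min,ud_max,rd_min,rd_max DOY bounds.
#' @return A `histogram_window` list.
#' @export
histogram_window <- function(ud_min = 50, ud_max = 170,
                             rd_min = 170, rd_max = 330) {
  stopifnot(ud_min < ud_max, ud_max <= rd_max, rd_min < rd_max)
  structure(list(ud_min = ud_min, ud_max = ud_max,
                 rd_min = rd_min, rd_max = rd_max),
            class = "histogram_window")
}

#' Automatic histogram window from the map itself
#'
#' Data-driven alternative to manual histogram inspection: for each of UD
#' and RD, the window is the distribution mode (binned by 5 days) plus/minus
#' `k` times the median absolute deviation.
#'
#' @param map A `pheno_map`.
#' @param k MAD multiplier (default 2).
#' @return A [histogram_window()].
#' @export
auto_histogram_window <- function(map, k = 2) {
  win1 <- function(x) {
    x <- x[is.finite(x)]
    br <- seq(floor(min(x) / 5) * 5, ceiling(max(x) / 5) * 5 + 5, by = 5)
    h <- graphics::hist(x, breaks = br, plot = FALSE)
    mode <- h$mids[which.max(h$counts)]
    c(mode - k * mad(x, center = mode), mode + k * mad(x, center = mode))
  }
  u <- win1(map$ud); r <- win1(map$rd)
  # windows may overlap; only ud_max <= rd_max is structurally required
  histogram_window(u[1], min(u[2], r[2]), min(r[1], r[2] - 1), r[2])
}

#' Classify map pixels by the UD/RD histogram windows
#'
#' Pixels whose UD or RD falls outside the acceptance windows are classed
#' `interspace` (weak/no-signal ground between canopies); the rest are
#' `vegetation`. GSL is kept only for vegetation pixels, and because the
#' windows enforce RD >= rd_min >= ud_max >= UD, no negative GSL survives
#' filtering.
#'
#' @param map A `pheno_map` from [fit_per_pixel()].
#' @param window A [histogram_window()] (or [auto_histogram_window()]).
#' @return The map with `class` filled in (`vegetation` / `interspace` /
#'   `excluded`) and `gsl` blanked outside the vegetation class.
#' @export
filter_histogram <- function(map, window = histogram_window()) {
  veg <- is.finite(map$ud) & is.finite(map$rd) &
    map$ud >= window$ud_min & map$ud <= window$ud_max &
    map$rd >= window$rd_min & map$rd <= window$rd_max
  out <- map
  out$class <- dplyr::case_when(
    map$class == "excluded" ~ "excluded",
    veg ~ "vegetation",
    .default = "interspace"
  )
  out$gsl[out$class != "vegetation"] <- NA_real_
  if (!any(out$class == "vegetation")) {
    warn("histogram filtering left an empty vegetation class")
  }
  structure(out, dims = attr(map, "dims"), class_map = attr(map, "class_map"),
            class = class(map))
}

#' Per-pixel seasonal GCC range
#'
#' Annual max minus min of each pixel's trajectory. By default the range is
#' taken on the smoothed (spline) series so single-sample spikes do not
#' inflate it; `smooth = FALSE` uses the raw daily extremes.
#'
#' @param trajectories A `pixel_trajectories` tibble.
#' @param smooth Use the smoothing spline (default `TRUE`).
#' @return A tibble `row`, `col`, `range_gcc`.
#' @export
gcc_range_map <- function(trajectories, smooth = TRUE) {
  pixels <- dplyr::group_split(trajectories, .data$row, .data$col)
  rows <- purrr::map(pixels, function(px) {
    ok <- !is.na(px$gcc)
    rng <- if (sum(ok) < 4) {
      NA_real_
    } else if (smooth && sum(ok) >= 20) {
      fit <- tryCatch(smooth.spline(px$doy[ok], px$gcc[ok],
                                    df = spline_df(sum(ok))),
                      error = function(e) NULL)
      if (is.null(fit)) diff(range(px$gcc[ok])) else {
        yg <- predict(fit, seq(min(px$doy[ok]), max(px$doy[ok]), by = 0.25))$y
        diff(range(yg))
      }
    } else diff(range(px$gcc[ok]))
    tibble::tibble(row = px$row[1], col = px$col[1], range_gcc = rng)
  })
  dplyr::bind_rows(rows)
}

# Exhaustive single-changepoint-in-mean search on a numeric vector:
# minimizes within-segment SSE over all splits.
best_mean_split <- function(x, min_seg = 1L) {
  n <- length(x)
  cs <- cumsum(x); cs2 <- cumsum(x^2)
  sse <- function(i, j) {
    m <- j - i + 1
    lo <- ifelse(i > 1, cs[pmax(i - 1, 1)], 0)
    lo2 <- ifelse(i > 1, cs2[pmax(i - 1, 1)], 0)
    pmax((cs2[j] - lo2) - (cs[j] - lo)^2 / m, 0)
  }
  ks <- min_seg:(n - min_seg)
  tot <- sse(1, ks) + sse(ks + 1, n)
  k <- ks[which.min(tot)]
  list(k = k, sse_split = min(tot), sse_null = sse(1, n))
}

#' Split interspace pixels into bare ground vs woody/shadow
#'
#' Orders the per-pixel GCC ranges of the interspace class ascending (the
#' empirical CDF ordering) and finds a single changepoint in the mean by
#' exhaustive within-segment SSE minimization. Because sorting makes any
#' split reduce the SSE (a sorted unimodal sample is cut roughly in half,
#' reducing SSE by a factor of ~3--4 regardless of structure), an SIC
#' penalty alone cannot reject the unimodal null: the split is accepted only
#' when it also reduces the SSE by at least `min_variance_ratio` (default 8,
#' above the unimodal sorted-data reduction and far below that of separated
#' mixtures). The lower segment is bare ground; the upper is woody material
#' and shadow.
#'
#' @param range_values Numeric vector of per-pixel GCC ranges (interspace
#'   class).
#' @param min_variance_ratio Minimum `SSE_null / SSE_split` for a changepoint
#'   to be accepted (default 8).
#' @return A list: `split` (GCC range value between the classes, `NA` when a
#'   single class is supported), `classes` (tibble `value`, `class`), and
#'   `summary` (per class median and 10th/90th percentiles).
#' @export
split_interspace <- function(range_values, min_variance_ratio = 8) {
  x <- sort(range_values[is.finite(range_values)])
  n <- length(x)
  if (n < 2) abort("need at least 2 interspace values")
  if (n < 20) warn("fewer than 20 interspace pixels; split may be unstable")
  bs <- best_mean_split(x)
  k <- bs$k
  accept <- bs$sse_null / max(bs$sse_split, 1e-12) > min_variance_ratio
  summarize_cls <- function(v, cls) {
    tibble::tibble(class = cls, n = length(v), median = median(v),
                   p10 = pheno_quantile(v, 0.1), p90 = pheno_quantile(v, 0.9))
  }
  if (!accept) {
    return(list(split = NA_real_,
                classes = tibble::tibble(value = x, class = "interspace"),
                summary = summarize_cls(x, "interspace")))
  }
  split_val <- (x[k] + x[k + 1]) / 2
  cls <- ifelse(x <= split_val, "bare-ground", "woody-shadow")
  list(split = split_val,
       classes = tibble::tibble(value = x, class = cls),
       summary = dplyr::bind_rows(
         summarize_cls(x[cls == "bare-ground"], "bare-ground"),
         summarize_cls(x[cls == "woody-shadow"], "woody-shadow")))
}

sse_of <- function(x, i, j) {
  v <- x[i:j]
  sum((v - mean(v))^2)
}

#' Write a phenophase map as per-pixel CSV
#'
#' @param map A `pheno_map`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pheno_map <- function(map, path) {
  utils::write.csv(as.data.frame(map), path, row.names = FALSE)
  invisible(path)
}
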