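# Synthetic scenes and GCC series with known ground truth, emulating a
# cold-desert camera deployment: 5 frames/day between 08:00 and 18:00,
# vegetation with low-amplitude (0.016--0.062 GCC) double-logistic seasons
# over baselines near 0.31--0.33, flat noisy interspace, and ephemeral
# winter/spring snow events.

#' Reference trajectory parameter presets
#'
#' Gu-model parameter sets whose noiseless phenophases (dense-grid truth)
#' reproduce the amplitude and date regimes typical of Great Basin plant
#' communities: sedge-dominated wet and mesic meadows, sagebrush canopy, and
#' evergreen pinyon/juniper canopies with very low amplitude.
#'
#' @return A named list of named parameter vectors usable with
#'   [gu_curve()] and [generate_gcc_series()].
#' @export
gu_presets <- function() {
  list(
    wet_meadow = c(y0 = 0.327, a1 = 0.07018, a2 = 0.06941, t1 = 142.7,
                   t2 = 216.4, b1 = 7.909, b2 = 19.81, c1 = 1, c2 = 1),
    mesic_meadow = c(y0 = 0.329, a1 = 0.05049, a2 = 0.05094, t1 = 133.7,
                     t2 = 212.3, b1 = 10.69, b2 = 28.47, c1 = 1, c2 = 1),
    sagebrush_canopy = c(y0 = 0.312, a1 = 0.02404, a2 = 0.02266, t1 = 137.9,
                         t2 = 230.8, b1 = 14.91, b2 = 15.19, c1 = 1, c2 = 1),
    pinyon = c(y0 = 0.333, a1 = 0.02126, a2 = 0.02392, t1 = 142.1,
               t2 = 287.5, b1 = 13.24, b2 = 38.17, c1 = 1, c2 = 1),
    juniper = c(y0 = 0.321, a1 = 0.04471, a2 = 0.03538, t1 = 145.1,
                t2 = 258.3, b1 = 16.96, b2 = 24.62, c1 = 1, c2 = 1),
    interspace = c(y0 = 0.308, a1 = 0.008, a2 = 0.0075, t1 = 135, t2 = 220,
                   b1 = 12, b2 = 16, c1 = 1, c2 = 1)
  )
}

#' Ground-truth phenophases of a noiseless Gu curve (dense-grid oracle)
#'
#' Computes UD/SD/DD/RD/GSL of an analytic Gu trajectory by brute force on a
#' dense day grid, with finite-difference derivatives and explicit line
#' intersections. Deliberately self-contained: it shares no code with the
#' model-fitting path, so fitted phenophases can be validated against it.
#'
#' @param params Gu parameter vector.
#' @param span Day range, default `c(1, 365)`.
#' @param step Grid step in days (default 0.01).
#' @param plateau Apply the plateau-line DD adjustment (default `TRUE`).
#' @return A named list with `UD, SD, DD, RD, gsl, min_gcc, max_gcc,
#'   range_gcc`.
#' @export
phenophase_truth <- function(params, span = c(1, 365), step = 0.01,
                             plateau = TRUE) {
  tg <- seq(span[1], span[2], by = step)
  yg <- gu_curve(tg, params)
  # central finite differences, one-sided at the ends
  dg <- c(diff(yg[1:2]) / step,
          (yg[-(1:2)] - yg[-c(length(yg) - 1, length(yg))]) / (2 * step),
          diff(yg[length(yg) - 1:0]) / step)
  ir <- which.max(dg); is <- which.min(dg)
  base <- min(yg); maxv <- max(yg)
  sr <- dg[ir]; ss <- dg[is]
  cross <- function(t0, y_at, slope, level) t0 + (level - y_at) / slope
  ud <- cross(tg[ir], yg[ir], sr, base)
  sd_ <- cross(tg[ir], yg[ir], sr, maxv)
  dd <- cross(tg[is], yg[is], ss, maxv)
  rd <- cross(tg[is], yg[is], ss, base)
  if (plateau && dd > sd_) {
    sel <- tg >= sd_ & tg <= dd
    if (sum(sel) >= 2) {
      X <- cbind(1, tg[sel])
      beta <- solve(crossprod(X), crossprod(X, yg[sel]))
      dd_adj <- (yg[is] - ss * tg[is] - beta[1]) / (beta[2] - ss)
      # flat plateau (no greendown): no adjustment
      if (is.finite(dd_adj) && abs(beta[2]) > 1e-6 &&
          dd_adj > sd_ && dd_adj <= rd) dd <- dd_adj
    }
  }
  list(UD = ud, SD = sd_, DD = dd, RD = rd, gsl = rd - ud,
       min_gcc = base, max_gcc = maxv, range_gcc = maxv - base)
}

# Red share of the non-green chromatic fraction used when synthesizing rcc
# and bcc alongside a target gcc; typical of soil/canopy scenes.
.red_fraction <- 0.54

rcc_bcc_from_gcc <- function(gcc) {
  rcc <- (1 - gcc) * .red_fraction
  list(rcc = rcc, bcc = 1 - gcc - rcc)
}

#' Generate a sub-daily GCC series from a Gu trajectory
#'
#' Emulates a season of camera sampling: `samples_per_day` frames per day
#' spaced between 08:00 and 18:00, GCC following the analytic Gu curve plus
#' Gaussian noise. The attached truth record carries the dense-grid oracle
#' phenophases of the noiseless curve.
#'
#' @param params Gu parameter vector (see [gu_presets()]).
#' @param days Integer days of year to sample (default `1:365`).
#' @param noise_sigma Gaussian noise SD in GCC units (default 0.003).
#' @param samples_per_day Frames per day (default 5).
#' @param seed RNG seed.
#' @return A sub-daily chromatic series tibble (`time, doy, roi, gcc, rcc,
#'   bcc, n_pixels`) with attributes `truth` (oracle phenophases and the
#'   parameters) and `aggregation = "sub-daily"`.
#' @export
generate_gcc_series <- function(params, days = 1:365, noise_sigma = 0.003,
                                samples_per_day = 5L, seed = 1L) {
  hours <- seq(8, 18, length.out = samples_per_day)
  doy <- rep(days, each = samples_per_day) +
    rep(hours, times = length(days)) / 24
  clean <- gu_curve(doy, params)
  if (any(clean <= 0 | clean >= 1)) {
    abort("parameters yield GCC outside (0, 1)")
  }
  set.seed(seed)
  gcc <- clean + rnorm(length(doy), 0, noise_sigma)
  other <- rcc_bcc_from_gcc(gcc)
  out <- tibble::tibble(
    time = time_from_doy(doy),
    doy = doy,
    roi = "synthetic",
    gcc = gcc, rcc = other$rcc, bcc = other$bcc,
    n_pixels = NA_integer_
  )
  attr(out, "truth") <- c(
    phenophase_truth(params, span = range(days)),
    list(params = params, noise_sigma = noise_sigma)
  )
  attr(out, "aggregation") <- "sub-daily"
  out
}

#' Ground truth attached to a synthetic series
#'
#' @param x A tibble produced by [generate_gcc_series()] (the attribute
#'   survives [inject_snow()]).
#' @return The truth record (list), or `NULL`.
#' @export
series_truth <- function(x) attr(x, "truth")

merge_spans <- function(spans) {
  m <- do.call(rbind, lapply(spans, function(s) sort(s[1:2])))
  m <- m[order(m[, 1]), , drop = FALSE]
  out <- m[1, , drop = FALSE]
  merged <- FALSE
  for (i in seq_len(nrow(m))[-1]) {
    last <- nrow(out)
    if (m[i, 1] <= out[last, 2]) {
      out[last, 2] <- max(out[last, 2], m[i, 2])
      merged <- TRUE
    } else out <- rbind(out, m[i, ])
  }
  if (merged) warn("overlapping snow spans merged")
  out
}

#' Inject ephemeral snow events into a series
#'
#' Samples on days inside the given spans have their GCC replaced by draws
#' from a low band (snow and the associated exposure flattening depress GCC
#' well below clean vegetation values); a logical `snow` truth column is
#' added for filter benchmarking.
#'
#' @param series A sub-daily chromatic series tibble.
#' @param spans List of `c(start_doy, end_doy)` day spans; overlapping spans
#'   are merged with a warning.
#' @param level Lower/upper bound of the snow GCC band
#'   (default `c(0.20, 0.27)`).
#' @param seed RNG seed.
#' @return The contaminated series with a `snow` column; other attributes
#'   (including truth) preserved.
#' @export
inject_snow <- function(series, spans, level = c(0.20, 0.27), seed = 1L) {
  if (length(spans) == 0) {
    series$snow <- FALSE
    return(series)
  }
  m <- merge_spans(spans)
  day <- floor(series$doy)
  hit <- rep(FALSE, nrow(series))
  for (i in seq_len(nrow(m))) hit <- hit | (day >= m[i, 1] & day <= m[i, 2])
  set.seed(seed)
  g <- series$gcc
  g[hit] <- runif(sum(hit), level[1], level[2])
  other <- rcc_bcc_from_gcc(g)
  out <- series
  out$gcc <- g; out$rcc <- other$rcc; out$bcc <- other$bcc
  out$snow <- hit
  out
}

#' Specify a synthetic camera scene
#'
#' @param width,height Frame size in pixels.
#' @param class_map Integer matrix (`height` x `width`) of 1-based class
#'   indices into `classes`; must cover every pixel.
#' @param classes Named list; each element is either
#'   `list(type = "gu", params = <Gu vector>)` for seasonal vegetation or
#'   `list(type = "flat", level = <GCC>)` for interspace.
#' @param days Integer days of year (default `1:365`).
#' @param images_per_day Frames per day (default 5).
#' @param noise_sigma Per-pixel, per-frame GCC noise SD (default 0.003).
#' @param snow_spans Optional list of snow day spans as in [inject_snow()].
#' @param seed RNG seed; identical seeds give identical scenes.
#' @param site Site label used in frame filenames.
#' @return A `scene_spec` list.
#' @export
scene_spec <- function(width, height, class_map, classes, days = 1:365,
                       images_per_day = 5L, noise_sigma = 0.003,
                       snow_spans = list(), seed = 1L, site = "site") {
  stopifnot(is.matrix(class_map), nrow(class_map) == height,
            ncol(class_map) == width, !anyNA(class_map),
            all(class_map %in% seq_along(classes)))
  for (cl in classes) {
    lv <- if (cl$type == "gu") gu_curve(days, cl$params) else cl$level
    if (any(lv <= 0 | lv >= 1)) abort("class trajectory leaves (0, 1) GCC")
  }
  structure(list(width = width, height = height, class_map = class_map,
                 classes = classes, days = days,
                 images_per_day = as.integer(images_per_day),
                 noise_sigma = noise_sigma, snow_spans = snow_spans,
                 seed = seed, site = site),
            class = "scene_spec")
}

scene_class_gcc <- function(spec, doy) {
  m <- vapply(spec$classes, function(cl) {
    if (cl$type == "gu") gu_curve(doy, cl$params) else rep(cl$level, length(doy))
  }, numeric(length(doy)))
  matrix(m, nrow = length(doy))
}

#' Per-pixel daily GCC trajectories of a scene, without rendering images
#'
#' Simulates what per-pixel extraction from the rendered frames would yield:
#' each pixel follows its class trajectory plus per-frame noise, aggregated
#' to daily means. Fast path for validating the spatial module.
#'
#' @param spec A [scene_spec()].
#' @return A `pixel_trajectories` long tibble (`row`, `col`, `doy`, `gcc`,
#'   0-based pixel coordinates) with attributes `dims`, `class_map` and
#'   `truth` (per-class oracle phenophases).
#' @export
simulate_pixel_trajectories <- function(spec) {
  set.seed(spec$seed)
  npx <- spec$height * spec$width
  ndays <- length(spec$days)
  cls <- as.vector(spec$class_map)              # column-major pixel order
  class_daily <- scene_class_gcc(spec, spec$days)  # ndays x nclass
  # mean of images_per_day noisy sub-daily samples == daily noise sigma/sqrt(k)
  daily <- class_daily[, cls, drop = FALSE] +
    matrix(rnorm(ndays * npx, 0, spec$noise_sigma / sqrt(spec$images_per_day)),
           ndays, npx)
  idx <- expand.grid(row = 0:(spec$height - 1), col = 0:(spec$width - 1))
  out <- tibble::tibble(
    row = rep(idx$row, each = ndays),
    col = rep(idx$col, each = ndays),
    doy = rep(spec$days, times = npx),
    gcc = as.vector(daily)
  )
  truth <- purrr::map(spec$classes, function(cl) {
    if (cl$type == "gu") {
      phenophase_truth(cl$params, span = range(spec$days))
    } else list(flat_level = cl$level)
  })
  structure(out,
            dims = c(spec$height, spec$width),
            class_map = spec$class_map,
            truth = truth,
            class = c("pixel_trajectories", class(out)))
}

#' Render a scene to timestamped image files plus truth maps
#'
#' Writes one PNG frame per acquisition. Digital numbers realize each
#' pixel's chromatic target at a fixed total brightness S = R+G+B = 450
#' (rounding error at most 0.5/450 per coordinate). Snow days are rendered
#' bright and chromatically flattened: the whole frame takes GCC from the
#' snow band at total brightness 600. Truth (class map and per-class
#' phenophases) is written as CSV alongside.
#'
#' @param spec A [scene_spec()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, a list with `frames` (paths), `class_map_csv`,
#'   `truth_csv`.
#' @export
render_scene <- function(spec, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(spec$seed)
  hours <- seq(8, 18, length.out = spec$images_per_day)
  snow_days <- integer()
  if (length(spec$snow_spans) > 0) {
    m <- merge_spans(spec$snow_spans)
    for (i in seq_len(nrow(m))) snow_days <- c(snow_days, m[i, 1]:m[i, 2])
  }
  cls <- as.vector(spec$class_map)
  paths <- character()
  for (d in spec$days) {
    for (h in hours) {
      doy <- d + h / 24
      snowy <- d %in% snow_days
      if (snowy) {
        g <- runif(length(cls), 0.20, 0.27)
        brightness <- 600
      } else {
        g <- scene_class_gcc(spec, doy)[1, cls] +
          rnorm(length(cls), 0, spec$noise_sigma)
        brightness <- 450
      }
      g <- pmin(pmax(g, 0.01), 0.99)
      oth <- rcc_bcc_from_gcc(g)
      G <- round(g * brightness); R <- round(oth$rcc * brightness)
      B <- brightness - G - R
      arr <- array(0, c(spec$height, spec$width, 3))
      arr[, , 1] <- matrix(pmin(R, 255), spec$height, spec$width)
      arr[, , 2] <- matrix(pmin(G, 255), spec$height, spec$width)
      arr[, , 3] <- matrix(pmin(pmax(B, 0), 255), spec$height, spec$width)
      t <- time_from_doy(doy)
      path <- file.path(dir, sprintf("%s_%s.png", spec$site,
                                     strftime(t, "%Y_%m_%d_%H%M", tz = "UTC")))
      png::writePNG(arr / 255, path)
      paths <- c(paths, path)
    }
  }
  idx <- expand.grid(row = 0:(spec$height - 1), col = 0:(spec$width - 1))
  cm <- tibble::tibble(row = idx$row, col = idx$col,
                       class = names(spec$classes)[cls])
  cm_path <- file.path(dir, "truth_class_map.csv")
  utils::write.csv(cm, cm_path, row.names = FALSE)
  truth <- purrr::imap(spec$classes, function(cl, nm) {
    if (cl$type == "gu") {
      ph <- phenophase_truth(cl$params, span = range(spec$days))
      tibble::tibble(class = nm, ud = ph$UD, sd = ph$SD, dd = ph$DD,
                     rd = ph$RD, gsl = ph$gsl, range_gcc = ph$range_gcc)
    } else {
      tibble::tibble(class = nm, ud = NA_real_, sd = NA_real_, dd = NA_real_,
                     rd = NA_real_, gsl = NA_real_, range_gcc = 0)
    }
  })
  truth_path <- file.path(dir, "truth_phenophases.csv")
  utils::write.csv(dplyr::bind_rows(truth), truth_path, row.names = FALSE)
  invisible(list(frames = paths, class_map_csv = cm_path,
                 truth_csv = truth_path))
}

#' Benchmark snow-event spans for a cold-desert winter
#'
#' Day spans emulating the snow climate of a Great Basin site: ephemeral
#' pulses from January to May and near-continuous (about 89% of days) cover
#' through November and December, with a few clean anchor days between
#' storms. About a quarter of all samples in a full-year series fall inside
#' the spans.
#'
#' @return A list of `c(start_doy, end_doy)` spans for [inject_snow()].
#' @export
snow_scenario_spans <- function() {
  list(c(4, 10), c(31, 38), c(52, 57), c(80, 86), c(110, 115), c(131, 134),
       c(305, 318), c(320, 332), c(334, 346), c(348, 360), c(362, 365))
}
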