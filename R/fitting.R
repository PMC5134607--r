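# Gu double-logistic fitting of daily GCC, residual-resampling uncertainty,
# and phenophase extraction.
#
# Model (Gu et al. 2009 form, 9 parameters):
#   y(t) = y0 + a1 / (1 + exp(-(t - t1)/b1))^c1
#             - a2 / (1 + exp(-(t - t2)/b2))^c2
# y0 baseline GCC; a1/a2 recovery and senescence amplitudes (GCC units);
# t1/t2 inflection days; b1/b2 rate scales (days); c1/c2 shape exponents.

gu_param_names <- c("y0", "a1", "a2", "t1", "t2", "b1", "b2", "c1", "c2")

#' Gu double-logistic curve and its derivative
#'
#' @param t Day of year (numeric vector).
#' @param params Named numeric vector/list with `y0, a1, a2, t1, t2, b1, b2,
#'   c1, c2`.
#' @return GCC values (`gu_curve`) or dGCC/dt (`gu_deriv`).
#' @export
gu_curve <- function(t, params) {
  p <- as.list(params)
  u1 <- exp(-(t - p$t1) / p$b1)
  u2 <- exp(-(t - p$t2) / p$b2)
  p$y0 + p$a1 / (1 + u1)^p$c1 - p$a2 / (1 + u2)^p$c2
}

#' @rdname gu_curve
#' @export
gu_deriv <- function(t, params) {
  p <- as.list(params)
  u1 <- exp(-(t - p$t1) / p$b1)
  u2 <- exp(-(t - p$t2) / p$b2)
  p$a1 * p$c1 * u1 / (p$b1 * (1 + u1)^(p$c1 + 1)) -
    p$a2 * p$c2 * u2 / (p$b2 * (1 + u2)^(p$c2 + 1))
}

# Bounds keep the optimizer out of unphysical corners: transition rate
# scales beyond ~60 days are not seasonal transitions, and inflection days
# may not wander far outside the observed span.
gu_bounds <- function(doy) {
  rng <- range(doy)
  list(
    lower = c(y0 = 0, a1 = 0, a2 = 0, t1 = rng[1] - 60, t2 = rng[1] - 60,
              b1 = 0.5, b2 = 0.5, c1 = 0.05, c2 = 0.05),
    upper = c(y0 = 1, a1 = 1, a2 = 1, t1 = rng[2] + 60, t2 = rng[2] + 60,
              b1 = 60, b2 = 60, c1 = 20, c2 = 20)
  )
}

gu_init <- function(doy, gcc) {
  q05 <- pheno_quantile(gcc, 0.05)
  q95 <- pheno_quantile(gcc, 0.95)
  mid <- (q05 + q95) / 2
  above <- doy[gcc >= mid]
  t1 <- if (length(above)) min(above) else pheno_quantile(doy, 0.35)
  t2 <- if (length(above)) max(above) else pheno_quantile(doy, 0.7)
  c(y0 = q05, a1 = max(q95 - q05, 1e-4), a2 = max(q95 - q05, 1e-4),
    t1 = t1, t2 = t2, b1 = 10, b2 = 10, c1 = 1, c2 = 1)
}

gu_fit_once <- function(doy, gcc, start, maxit = 400) {
  resid_fn <- function(p) gcc - gu_curve(doy, setNames(p, gu_param_names))
  bnd <- gu_bounds(doy)
  fit <- tryCatch(
    minpack.lm::nls.lm(par = pmin(pmax(start, bnd$lower), bnd$upper),
                       lower = bnd$lower, upper = bnd$upper, fn = resid_fn,
                       control = minpack.lm::nls.lm.control(maxiter = maxit)),
    error = function(e) NULL)
  if (is.null(fit)) return(NULL)
  list(params = setNames(coef(fit), gu_param_names),
       rss = fit$deviance, info = fit$info)
}

#' Fit the Gu double-logistic model to a daily GCC series
#'
#' Least-squares fit (Levenberg--Marquardt) with a data-driven start --
#' baseline at the 5th percentile, amplitudes at the 5th--95th percentile
#' span, inflections at the first/last midpoint crossings -- plus jittered
#' restarts under a fixed seed; the lowest-RSS solution wins. Deterministic
#' given the data and `seed`.
#'
#' @param daily Daily series tibble with `doy` and `gcc` (e.g. from
#'   [max_filter()]).
#' @param restarts Number of jittered restarts (default 5).
#' @param seed Seed for the restart jitter (default 1).
#' @return A `gu_fit` object: parameters, fitted values, residuals, `rmse`,
#'   `converged` and `degenerate` flags.
#' @export
fit_gu <- function(daily, restarts = 5L, seed = 1L) {
  daily <- daily[!is.na(daily$gcc), , drop = FALSE]
  n <- nrow(daily)
  if (n < 20 || diff(range(daily$doy)) < 120) {
    abort("fit_gu needs >= 20 daily values spanning >= 120 days")
  }
  doy <- daily$doy; gcc <- daily$gcc
  start0 <- gu_init(doy, gcc)
  starts <- list(start0)
  if (restarts > 0) {
    set.seed(seed)
    span <- diff(range(doy))
    for (i in seq_len(restarts)) {
      s <- start0
      s["t1"] <- s["t1"] + runif(1, -0.1, 0.1) * span
      s["t2"] <- s["t2"] + runif(1, -0.1, 0.1) * span
      s["b1"] <- s["b1"] * exp(runif(1, -0.7, 0.7))
      s["b2"] <- s["b2"] * exp(runif(1, -0.7, 0.7))
      s["c1"] <- s["c1"] * exp(runif(1, -0.5, 0.5))
      s["c2"] <- s["c2"] * exp(runif(1, -0.5, 0.5))
      starts[[i + 1]] <- s
    }
  }
  # two informed extra starts with the senescence inflection well inside
  # the span: when late-season data are sparse (e.g. snow-filtered), the
  # jittered starts can all collapse onto an optimum whose senescence lies
  # beyond the data
  s_in <- start0
  s_in["t2"] <- pheno_quantile(doy, 0.75); s_in["b2"] <- 10
  s_in2 <- start0
  s_in2["t1"] <- pheno_quantile(doy, 0.3); s_in2["b1"] <- 8
  s_in2["t2"] <- pheno_quantile(doy, 0.85); s_in2["b2"] <- 15
  starts <- c(starts, list(s_in, s_in2))
  fits <- purrr::compact(purrr::map(starts, ~ gu_fit_once(doy, gcc, .x)))
  if (length(fits) == 0) {
    abort("Gu fit failed from every start")
  }
  # When the data only partially constrain the senescence limb (e.g. a
  # filtered-out tail) several restarts reach statistically
  # indistinguishable optima. Among candidates within 1% of the best RSS,
  # prefer fits that formally converged and whose derivative extrema are
  # interior to the span with the right signs (interpretable seasonality).
  rss_all <- purrr::map_dbl(fits, "rss")
  rss_min <- min(rss_all)
  near <- fits[rss_all <= rss_min * 1.01]
  grid <- seq(min(doy), max(doy), length.out = 512)
  seasonal_ok <- function(f) {
    dg <- gu_deriv(grid, f$params)
    ir <- which.max(dg); is <- which.min(dg)
    !(ir %in% c(1L, 512L)) && !(is %in% c(1L, 512L)) &&
      dg[ir] > 0 && dg[is] < 0
  }
  rank3 <- purrr::map_dbl(near, function(f) {
    conv <- f$info %in% 1:3
    seas <- seasonal_ok(f)
    -(2 * conv + seas)  # converged+seasonal best, then converged, then seasonal
  })
  near <- near[order(rank3, purrr::map_dbl(near, "rss"))]
  best <- near[[1]]
  fitted <- gu_curve(doy, best$params)
  res <- gcc - fitted
  amp <- diff(range(fitted))
  structure(list(
    params = best$params,
    data = tibble::tibble(doy = doy, gcc = gcc),
    fitted = fitted,
    residuals = res,
    rss = best$rss,
    rmse = sqrt(mean(res^2)),
    converged = best$info %in% 1:3,
    degenerate = amp < 1e-3,
    seed = seed
  ), class = "gu_fit")
}

#' @export
print.gu_fit <- function(x, ...) {
  cat("<gu_fit>", if (!x$converged) "(not converged)",
      if (x$degenerate) "(degenerate: no seasonal amplitude)", "\n")
  print(round(x$params, 4))
  cat(sprintf("n = %d, rmse = %.5f GCC\n", nrow(x$data), x$rmse))
  invisible(x)
}

#' @export
tidy.gu_fit <- function(x, ...) {
  tibble::tibble(term = gu_param_names, estimate = unname(x$params))
}

#' @export
glance.gu_fit <- function(x, ...) {
  tibble::tibble(n = nrow(x$data), rss = x$rss, rmse = x$rmse,
                 converged = x$converged, degenerate = x$degenerate)
}

#' Extract phenophase dates from a fitted Gu curve
#'
#' Applies the Gu line-intersection geometry to the fitted curve: tangents at
#' the extrema of the first derivative (green-up and senescence slopes),
#' horizontal baseline and max-line at the curve minimum and maximum, and a
#' plateau line fit between SD and the provisional DD to accommodate the
#' mid-season greendown. UD/SD intersect the recovery tangent with the
#' baseline/max-line; DD intersects the senescence tangent with the plateau
#' line; RD with the baseline. GSL = RD - UD.
#'
#' @param fit A `gu_fit`.
#' @param plateau Apply the plateau-line adjustment to DD (default `TRUE`).
#' @param grid_step Evaluation grid step in days (default 0.1).
#' @return A `pheno_phases` object (print or `tidy()` it), with `NA`
#'   dates and a diagnostic `flag` when the fit has no usable seasonal cycle.
#' @export
extract_phenophases <- function(fit, plateau = TRUE, grid_step = 0.1) {
  if (fit$degenerate) {
    warn("degenerate fit: no phenophases extracted")
  }
  rng <- range(fit$data$doy)
  tg <- seq(rng[1], rng[2], by = grid_step)
  yg <- gu_curve(tg, fit$params)
  dg <- gu_deriv(tg, fit$params)
  ph <- phases_from_grid(tg, yg, dg, plateau = plateau)
  structure(ph, class = "pheno_phases")
}

#' @export
print.pheno_phases <- function(x, ...) {
  cat("<pheno_phases>", if (x$flag != "ok") paste0("[", x$flag, "]"), "\n")
  cat(sprintf("  UD %.1f  SD %.1f  DD %.1f  RD %.1f  GSL %.1f days\n",
              x$UD, x$SD, x$DD, x$RD, x$gsl))
  cat(sprintf("  GCC min %.4f  max %.4f  range %.4f\n",
              x$min_gcc, x$max_gcc, x$range_gcc))
  invisible(x)
}

#' @export
tidy.pheno_phases <- function(x, ...) phases_as_tibble(x)

#' Residual-resampling uncertainty ensemble for a Gu fit
#'
#' Emulates the replication scheme used with camera greenness series: each
#' observation is perturbed by an independent draw from a uniform
#' distribution over the residual envelope `[min(residuals),
#' max(residuals)]` of the original fit, the model is refit (warm-started at
#' the original parameters), and phenophases are extracted; replicates whose
#' refit fails or yields no seasonal cycle are dropped and counted.
#'
#' @param fit A converged `gu_fit`.
#' @param n Number of replications (default 1000).
#' @param seed RNG seed; the ensemble is reproducible given the seed.
#' @param plateau Passed to [extract_phenophases()].
#' @return A `pheno_ensemble`: tibble of per-replicate `ud, sd, dd, rd, gsl`
#'   plus the residual envelope and drop count.
#' @export
estimate_uncertainty <- function(fit, n = 1000L, seed = 1L, plateau = TRUE) {
  stopifnot(inherits(fit, "gu_fit"), n >= 2)
  if (!fit$converged) abort("estimate_uncertainty requires a converged fit")
  env <- range(fit$residuals)
  doy <- fit$data$doy
  gcc <- fit$data$gcc
  rng <- range(doy)
  tg <- seq(rng[1], rng[2], by = 0.1)
  set.seed(seed)
  draws <- matrix(runif(n * length(gcc), env[1], env[2]), nrow = n)
  reps <- purrr::map(seq_len(n), function(i) {
    y <- gcc + draws[i, ]
    f <- gu_fit_once(doy, y, fit$params, maxit = 120)
    if (is.null(f) || !(f$info %in% 1:3)) return(NULL)
    yg <- gu_curve(tg, f$params)
    dg <- gu_deriv(tg, f$params)
    ph <- phases_from_grid(tg, yg, dg, plateau = plateau)
    if (ph$flag != "ok" || !is.finite(ph$UD)) return(NULL)
    tibble::tibble(replicate = i, ud = ph$UD, sd = ph$SD, dd = ph$DD,
                   rd = ph$RD, gsl = ph$gsl,
                   min_gcc = ph$min_gcc, max_gcc = ph$max_gcc)
  })
  dropped <- sum(purrr::map_lgl(reps, is.null))
  if (dropped > 0.2 * n) {
    abort(sprintf("uncertainty analysis unstable: %d of %d replicates failed",
                  dropped, n))
  }
  structure(list(
    replicates = dplyr::bind_rows(reps),
    n_requested = as.integer(n),
    n_dropped = as.integer(dropped),
    residual_envelope = env,
    seed = seed
  ), class = "pheno_ensemble")
}

#' @export
print.pheno_ensemble <- function(x, ...) {
  cat(sprintf("<pheno_ensemble: %d/%d replicates, envelope [%.4f, %.4f]>\n",
              nrow(x$replicates), x$n_requested,
              x$residual_envelope[1], x$residual_envelope[2]))
  invisible(x)
}

#' @export
tidy.pheno_ensemble <- function(x, ...) x$replicates

#' Median phenophases with 10th--90th percentile intervals
#'
#' Summarizes an uncertainty ensemble: per-phenophase median and 10th/90th
#' percentiles (linear-interpolation quantiles). GSL is summarized from the
#' per-replicate GSL distribution (RD - UD within each replicate), so its
#' median can differ from median RD minus median UD by a day.
#'
#' @param ensemble A `pheno_ensemble`.
#' @return A tibble with columns `phase` (`UD, SD, DD, RD, GSL`), `median`,
#'   `ci_lower` (10th) and `ci_upper` (90th percentile).
#' @export
phenophase_confidence <- function(ensemble) {
  reps <- ensemble$replicates
  if (nrow(reps) < 2) abort("need >= 2 surviving replicates")
  long <- tidyr::pivot_longer(
    reps[, c("ud", "sd", "dd", "rd", "gsl")],
    dplyr::everything(), names_to = "phase", values_to = "doy")
  out <- long |>
    dplyr::group_by(phase = toupper(.data$phase)) |>
    dplyr::summarise(
      median = median(.data$doy),
      ci_lower = pheno_quantile(.data$doy, 0.1),
      ci_upper = pheno_quantile(.data$doy, 0.9),
      .groups = "drop")
  out[match(c("UD", "SD", "DD", "RD", "GSL"), out$phase), ]
}

#' One-row ROI summary in standard column order
#'
#' Builds the publication-style per-ROI record: median and interval per
#' phenophase, growing season length, and the annual minimum, maximum and
#' range of the fitted GCC curve.
#'
#' @param confidence Output of [phenophase_confidence()] (or of
#'   `tidy(extract_phenophases(...))` reshaped the same way).
#' @param fit The `gu_fit` the confidence summary came from.
#' @param site Site/ROI label.
#' @return A one-row tibble: `site`, then `ud, sd, dd, rd, gsl` each with
#'   `_lo`/`_hi` 10th/90th columns, then `min_gcc`, `max_gcc`, `range_gcc`.
#' @export
summarize_roi <- function(confidence, fit, site = "roi") {
  cols <- purrr::imap(c(ud = "UD", sd = "SD", dd = "DD", rd = "RD", gsl = "GSL"),
    function(ph, nm) {
      r <- confidence[confidence$phase == ph, ]
      setNames(list(r$median, r$ci_lower, r$ci_upper),
               paste0(nm, c("", "_lo", "_hi")))
    })
  fitted_min <- min(fit$fitted)
  fitted_max <- max(fit$fitted)
  dplyr::bind_cols(
    tibble::tibble(site = site),
    tibble::as_tibble(purrr::flatten(unname(cols))),
    tibble::tibble(min_gcc = fitted_min, max_gcc = fitted_max,
                   range_gcc = fitted_max - fitted_min)
  )
}

#' Write fitted Gu parameters as JSON
#'
#' @param fit A `gu_fit`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fit_json <- function(fit, path) {
  jsonlite::write_json(
    list(params = as.list(fit$params), rmse = fit$rmse, rss = fit$rss,
         converged = fit$converged, degenerate = fit$degenerate,
         n = nrow(fit$data)),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
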