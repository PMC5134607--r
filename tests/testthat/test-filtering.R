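subdaily <- function(gcc, doy = seq_along(gcc)) {
  s <- tibble::tibble(doy = doy, gcc = gcc)
  attr(s, "aggregation") <- "sub-daily"
  s
}

test_that("night filter removes strictly-below-threshold samples and is idempotent", {
  s <- subdaily(c(0.15, 0.35, 0.19))
  out <- night_filter(s, 0.2)
  expect_equal(out$gcc, 0.35)
  expect_equal(filter_report(out)$night$n_removed, 2)

  all_ok <- subdaily(c(0.25, 0.3, 0.2))   # boundary value retained
  expect_equal(night_filter(all_ok)$gcc, c(0.25, 0.3, 0.2))

  once <- night_filter(s, 0.2)
  twice <- night_filter(once, 0.2, override = TRUE)
  expect_equal(twice$gcc, once$gcc)
})

test_that("the chain refuses out-of-order filters unless overridden", {
  s <- generate_gcc_series(gu_presets()$wet_meadow, seed = 1)
  daily <- max_filter(s)
  expect_error(night_filter(daily), "filter order")
  expect_error(spline_filter(daily), "filter order")
  expect_no_error(night_filter(daily, override = TRUE))
})

test_that("CDF breakpoint recovers a snow threshold inside the band gap", {
  set.seed(7)
  g <- c(runif(30, 0.20, 0.26), runif(170, 0.30, 0.36))
  th <- snow_threshold_from_cdf(g)
  expect_true(th >= 0.26 && th <= 0.30)
  # matches the exhaustive single-breakpoint least-squares oracle
  orc <- oracle_single_breakpoint(g, min_seg = max(4, ceiling(0.05 * 200)))
  expect_equal(th, orc$threshold, tolerance = 1e-12)
})

test_that("no breakpoint is reported for unstructured or tiny samples", {
  set.seed(8)
  expect_true(is.na(snow_threshold_from_cdf(runif(200, 0.30, 0.36))))
  expect_true(is.na(snow_threshold_from_cdf(runif(10))))
  expect_true(is.na(snow_threshold_from_cdf(rep(0.33, 50))))
  # clean seasonal series: the lower-range CDF bend of real phenology is
  # flat-to-steep, not a snow signature
  s <- generate_gcc_series(gu_presets()$wet_meadow, noise_sigma = 0.005,
                           seed = 3)
  expect_true(is.na(snow_threshold_from_cdf(s)))
})

test_that("snow threshold separates classes across simulated contamination levels", {
  hits <- 0
  n_runs <- 30
  for (i in seq_len(n_runs)) {
    set.seed(i)
    frac <- runif(1, 0.1, 0.3)
    n <- 400
    ns <- round(frac * n)
    gap <- runif(1, 0.04, 0.08)
    g <- c(runif(ns, 0.20, 0.26), runif(n - ns, 0.26 + gap, 0.32 + gap))
    th <- snow_threshold_from_cdf(g)
    if (!is.na(th) && th > 0.26 && th < 0.26 + gap) hits <- hits + 1
  }
  expect_gte(hits / n_runs, 0.9)
})

test_that("snow/night filter removes the snow cluster and falls back to the fixed filter", {
  set.seed(7)
  s <- subdaily(c(runif(30, 0.21, 0.26), runif(170, 0.30, 0.36)),
                doy = seq(1, 40, length.out = 200))
  out <- snow_night_filter(s)
  rep <- filter_report(out)$night
  expect_equal(rep$n_removed, 30)
  expect_true(all(out$gcc >= 0.30))
  expect_false(is.na(rep$snow_threshold))

  # no breakpoint -> identical to the fixed night filter at 0.2
  set.seed(9)
  flat <- subdaily(runif(100, 0.18, 0.40), doy = seq(1, 25, length.out = 100))
  a <- snow_night_filter(flat)
  b <- night_filter(flat, 0.2)
  expect_equal(a$gcc, b$gcc)

  # floor: a data-driven threshold below 0.2 must not relax the night filter
  set.seed(10)
  low <- subdaily(c(runif(40, 0.05, 0.12), runif(160, 0.17, 0.24)),
                  doy = seq(1, 40, length.out = 200))
  outl <- snow_night_filter(low)
  expect_true(all(outl$gcc >= 0.2))
})

test_that("spline filter rejects downward dips but not smooth trends or spikes", {
  # single deep dip on a flat series
  s1 <- subdaily(c(rep(0.33, 24), 0.25, rep(0.33, 25)),
                 doy = seq(1, 25, length.out = 50))
  out1 <- spline_filter(s1)
  expect_false(any(out1$gcc == 0.25))
  expect_equal(nrow(out1), 49)

  # smooth monotone series: identity
  d <- seq(1, 50, length.out = 80)
  s2 <- subdaily(0.3 + 0.0008 * d, doy = d)
  expect_equal(nrow(spline_filter(s2)), 80)

  # two isolated ~6-sigma dips in noise: both removed within 2 iterations
  set.seed(4)
  d3 <- seq(1, 40, length.out = 60)
  g3 <- 0.33 + rnorm(60, 0, 0.002)
  g3[c(20, 45)] <- g3[c(20, 45)] - 0.012
  out3 <- spline_filter(subdaily(g3, doy = d3))
  expect_false(any(out3$gcc %in% g3[c(20, 45)]))

  # upward spike retained: only greenness drops are artifacts
  s4 <- subdaily(c(rep(0.33, 24), 0.41, rep(0.33, 25)),
                 doy = seq(1, 25, length.out = 50))
  expect_equal(nrow(spline_filter(s4)), 50)

  # too few samples: identity with warning
  expect_warning(tiny <- spline_filter(subdaily(rep(0.3, 5))), "too few")
  expect_equal(nrow(tiny), 5)
})

test_that("max filter matches the linear-interpolation window percentile", {
  s <- subdaily(c(0.30, 0.32, 0.40), doy = c(10.2, 10.5, 10.8))
  out <- max_filter(s)
  expect_equal(out$gcc[out$doy == 10], 0.384)

  const <- subdaily(rep(0.31, 15), doy = rep(3:7, each = 3) + 0.4)
  expect_equal(unique(max_filter(const)$gcc), 0.31)

  single <- subdaily(0.29, doy = 42.5)
  expect_equal(max_filter(single)$gcc, 0.29)
})

test_that("max filter equals the brute-force oracle and respects the window max", {
  for (i in 1:5) {
    set.seed(i)
    n <- 120
    doy <- sort(runif(n, 1, 30))
    g <- runif(n, 0.25, 0.45)
    s <- subdaily(g, doy = doy)
    out <- max_filter(s)
    orc <- oracle_window_percentile(doy, g)
    expect_equal(out$doy, orc$doy)
    expect_equal(out$gcc, orc$gcc, tolerance = 1e-12)
    # monotonicity: output never exceeds the window maximum
    day <- floor(doy)
    for (j in seq_len(nrow(out))) {
      expect_lte(out$gcc[j], max(g[day >= out$doy[j] - 1 & day <= out$doy[j] + 1]))
    }
  }
})

test_that("3-day moving average handles edges and gaps", {
  expect_equal(moving_average_3day(c(1, 2, 3, 4)), c(1.5, 2, 3, 3.5))
  expect_equal(moving_average_3day(rep(2, 6)), rep(2, 6))
  df <- data.frame(date = c(1, 2, 4), value = c(1, 2, 4))
  out <- moving_average_3day(df)
  expect_equal(out$smoothed, c(1.5, 1.5, 4))  # day 4 has no present neighbours
  dfna <- data.frame(date = 1:3, value = c(1, NA, 3))
  expect_equal(moving_average_3day(dfna)$smoothed[2], 2)
})

test_that("full filter chain yields a daily series with stage reports", {
  s <- generate_gcc_series(gu_presets()$wet_meadow, seed = 5)
  s <- inject_snow(s, list(c(20, 40)), seed = 5)
  daily <- filter_chain(s)
  expect_equal(attr(daily, "aggregation"), "daily")
  reps <- filter_report(daily)
  expect_named(reps, c("night", "spline", "max"))
  expect_equal(reps$night$n_input, nrow(s))
  expect_true(all(diff(daily$doy) >= 1))
})
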