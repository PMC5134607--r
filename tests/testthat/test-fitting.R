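test_that("Gu parameters are recovered from noiseless daily curves", {
  for (nm in c("wet_meadow", "pinyon")) {
    p <- gu_presets()[[nm]]
    fit <- fit_gu(make_daily(p))
    expect_true(fit$converged)
    expect_false(fit$degenerate)
    expect_lt(max(abs((fit$params - p) / p)), 0.01)
    expect_lt(fit$rmse, 1e-6)
  }
})

test_that("a constant series yields a degenerate near-zero-amplitude fit", {
  fit <- fit_gu(tibble::tibble(doy = 1:200, gcc = rep(0.33, 200)))
  expect_true(fit$degenerate)
  expect_lt(fit$params[["a1"]], 1e-3)
  expect_lt(fit$params[["a2"]], 1e-3)
})

test_that("fit rmse stays at the noise level", {
  daily <- make_daily(gu_presets()$wet_meadow, noise_sigma = 0.002, seed = 9)
  fit <- fit_gu(daily)
  expect_lt(fit$rmse, 0.004)
})

test_that("fitting is deterministic given data and seed", {
  daily <- make_daily(gu_presets()$juniper, noise_sigma = 0.003, seed = 2)
  f1 <- fit_gu(daily, seed = 7)
  f2 <- fit_gu(daily, seed = 7)
  expect_identical(f1$params, f2$params)
})

test_that("tidy and glance expose the fit in broom style", {
  fit <- fit_gu(make_daily(gu_presets()$wet_meadow))
  td <- tidy(fit)
  expect_named(td, c("term", "estimate"))
  expect_equal(nrow(td), 9)
  gl <- glance(fit)
  expect_true(all(c("rmse", "converged", "n") %in% names(gl)))
  expect_equal(gl$n, 365)
})

test_that("phenophases match the dense-grid line-intersection oracle", {
  for (nm in names(gu_presets())[1:5]) {
    p <- gu_presets()[[nm]]
    fit <- fit_gu(make_daily(p))
    ph <- extract_phenophases(fit)
    orc <- oracle_phases(p)
    expect_lt(abs(ph$UD - orc$UD), 0.5)
    expect_lt(abs(ph$SD - orc$SD), 0.5)
    expect_lt(abs(ph$DD - orc$DD), 0.5)
    expect_lt(abs(ph$RD - orc$RD), 0.5)
    # ordering and the GSL identity
    expect_true(ph$UD <= ph$SD && ph$SD <= ph$DD && ph$DD <= ph$RD)
    expect_equal(ph$gsl, ph$RD - ph$UD)
    expect_equal(ph$range_gcc, ph$max_gcc - ph$min_gcc)
  }
})

test_that("a symmetric season has mirrored transition intervals", {
  psym <- c(y0 = 0.32, a1 = 0.05, a2 = 0.05, t1 = 140, t2 = 220,
            b1 = 10, b2 = 10, c1 = 1, c2 = 1)
  ph <- extract_phenophases(fit_gu(make_daily(psym)))
  expect_equal(ph$SD - ph$UD, ph$RD - ph$DD, tolerance = 0.05)
})

test_that("the plateau line delays DD past the max-line crossing under greendown", {
  # with mid-season greendown the curve leaves the max-line early, so the
  # provisional (max-line) DD is premature; intersecting the senescence
  # tangent with the fitted (declining) plateau line moves DD later, toward
  # the real departure from the plateau trend
  pgd <- c(y0 = 0.32, a1 = 0.08, a2 = 0.08, t1 = 130, t2 = 230,
           b1 = 6, b2 = 25, c1 = 1, c2 = 1)
  fit <- fit_gu(make_daily(pgd))
  with_pl <- extract_phenophases(fit, plateau = TRUE)
  without <- extract_phenophases(fit, plateau = FALSE)
  expect_lt(with_pl$plateau_slope, 0)
  expect_gte(with_pl$DD, without$DD)
  # the plateau line lies below the max-line where the senescence tangent
  # crosses it
  plateau_at_dd <- with_pl$plateau_intercept +
    with_pl$plateau_slope * with_pl$DD
  expect_lt(plateau_at_dd, with_pl$maxline)
  # and DD stays within the season
  expect_true(with_pl$SD < with_pl$DD && with_pl$DD < with_pl$RD)
})

test_that("the uncertainty ensemble is reproducible and degenerate when noiseless", {
  fit <- fit_gu(make_daily(gu_presets()$wet_meadow))
  # zero-residual input: every replicate identical, zero-width intervals
  ens0 <- estimate_uncertainty(fit, n = 10, seed = 3)
  expect_lt(diff(range(ens0$replicates$ud)), 1e-6)
  cf0 <- phenophase_confidence(ens0)
  expect_equal(cf0$ci_lower, cf0$ci_upper, tolerance = 1e-6)

  daily <- make_daily(gu_presets()$wet_meadow, noise_sigma = 0.003, seed = 4)
  fitn <- fit_gu(daily)
  e1 <- estimate_uncertainty(fitn, n = 50, seed = 11)
  e2 <- estimate_uncertainty(fitn, n = 50, seed = 11)
  expect_identical(e1$replicates, e2$replicates)
  expect_equal(nrow(e1$replicates) + e1$n_dropped, 50)
})

test_that("confidence summaries are the quantiles of the replicate ensemble", {
  reps <- tibble::tibble(replicate = 1:10,
                         ud = c(120:129), sd = c(150:159), dd = 180:189,
                         rd = 250:259, gsl = (250:259) - (120:129),
                         min_gcc = 0.32, max_gcc = 0.38)
  ens <- structure(list(replicates = reps, n_requested = 10L, n_dropped = 0L,
                        residual_envelope = c(-0.01, 0.01), seed = 1L),
                   class = "pheno_ensemble")
  cf <- phenophase_confidence(ens)
  ud <- cf[cf$phase == "UD", ]
  expect_equal(ud$median, median(120:129))
  expect_equal(ud$ci_lower, unname(quantile(120:129, 0.1, type = 7)))
  expect_equal(ud$ci_upper, unname(quantile(120:129, 0.9, type = 7)))
  # GSL summarized from the per-replicate distribution
  expect_equal(cf[cf$phase == "GSL", ]$median, 130)
})

test_that("median phenophases from the ensemble stay close to generator truth", {
  p <- gu_presets()$wet_meadow
  truth <- phenophase_truth(p)
  daily <- make_daily(p, noise_sigma = 0.003, seed = 21)
  fit <- fit_gu(daily)
  ens <- estimate_uncertainty(fit, n = 60, seed = 21)
  cf <- phenophase_confidence(ens)
  expect_lt(abs(cf[cf$phase == "UD", ]$median - truth$UD), 3)
  expect_lt(abs(cf[cf$phase == "RD", ]$median - truth$RD), 3)
})

test_that("ROI summary rows carry publication columns and the range identity", {
  p <- gu_presets()$wet_meadow
  fit <- fit_gu(make_daily(p, noise_sigma = 0.002, seed = 2))
  ens <- estimate_uncertainty(fit, n = 40, seed = 2)
  row <- summarize_roi(phenophase_confidence(ens), fit, site = "wet meadow")
  expect_equal(names(row)[1:4], c("site", "ud", "ud_lo", "ud_hi"))
  expect_equal(row$range_gcc, row$max_gcc - row$min_gcc)
  expect_equal(row$site, "wet meadow")
  expect_true(row$gsl_lo <= row$gsl && row$gsl <= row$gsl_hi)
})
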