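# phenodesert

Phenology from repeat digital camera imagery of **low-amplitude, semi-arid
vegetation** — sagebrush steppe, pinyon–juniper woodland, cold-desert
meadows — where the seasonal greenness signal is an order of magnitude
weaker than in the forests most phenocam tooling was built for, and where
ephemeral snow, shadows and bare soil routinely break naive processing.

For each image the package computes the green chromatic coordinate

    GCC = G_DN / (R_DN + G_DN + B_DN)

over polygon regions of interest (ROIs), and then:

* **cleans** the sub-daily series with a fixed-order filter chain —
  night filter (GCC < 0.2), an **automated snow/night filter** that finds a
  data-driven lower threshold from a breakpoint in the cumulative
  distribution of GCC (exhaustive segmented regression, BIC model
  selection, and a slope-ratio rule that distinguishes a sparse snow
  cluster from the natural bend of a clean seasonal CDF), a
  downward-outlier smoothing-spline filter, and a 3-day moving-window
  90th-percentile ("max") filter to daily resolution;
* **fits** the 9-parameter Gu double-logistic model
  `y(t) = y0 + a1/(1+exp(-(t-t1)/b1))^c1 - a2/(1+exp(-(t-t2)/b2))^c2`
  and dates four phenophases by line intersection — upturn (UD),
  stabilization (SD), downturn (DD, adjusted by a mid-season *plateau
  line* to handle greendown) and recession (RD), with growing season
  length GSL = RD − UD — plus residual-resampling **uncertainty**
  (uniform draws over the residual envelope, 1000 refits, 10th–90th
  percentile intervals around median dates);
* **maps** phenology per pixel with smoothing-spline fits and the same
  phenophase geometry, separates vegetation from bare interspace by
  UD/RD histogram windows, and splits the interspace into bare ground vs
  woody/shadow by a mean changepoint on sorted per-pixel GCC ranges;
* **simulates** full camera deployments (5 frames/day, PNG images,
  analytic Gu trajectories, flat interspace, snow events) with
  dense-grid oracle ground truth, so the whole chain is testable without
  field data.

Functions take a data frame first and return tibbles; fitted objects have
`tidy()`/`glance()` methods and every result type has an `autoplot()`.

## Worked example

A wet-meadow-regime season (seasonal amplitude 0.062 GCC over a 0.327
baseline; true UD 127, RD 257) sampled 5×/day and contaminated with a
realistic snow winter, then processed end to end:

```r
library(phenodesert)

s     <- generate_gcc_series(gu_presets()$wet_meadow, seed = 42)
s     <- inject_snow(s, snow_scenario_spans(), seed = 42)
daily <- filter_chain(s)          # snow/night -> spline -> max
filter_report(daily)$night[c("n_input", "n_removed", "threshold")]
#> $n_input   [1] 1825
#> $n_removed [1] 475
#> $threshold [1] 0.294        # data-driven snow threshold (band gap is 0.27-0.32)

fit  <- fit_gu(daily)
ens  <- estimate_uncertainty(fit, n = 200, seed = 42)
phenophase_confidence(ens)
#> # A tibble: 5 x 4
#>   phase median ci_lower ci_upper
#>   <chr>  <dbl>    <dbl>    <dbl>
#> 1 UD      126.     126.     127.
#> 2 SD      156.     155.     156.
#> 3 DD      187.     186.     188.
#> 4 RD      256.     255.     258.
#> 5 GSL     130.     128.     132.
```

Despite a quarter of the samples being snow, the filter recovers a
threshold inside the contamination gap and the fitted phenophases land
within a day of the generator truth: median UD day 126 (true 127), RD 256
(true 257), GSL 130 days, and a fitted GCC range of 0.063 (true 0.062).
`summarize_roi()` turns this into the standard one-row site summary
(site, UD/SD/DD/RD/GSL each with 10th–90th bounds, min/max/range GCC);
`plot_phenophases(fit, phenophase_confidence(ens))` draws the fitted curve
with dated transitions.

A bundled reference table of published-style community summaries for eight
Great Basin ROIs is at
`system.file("extdata", "cold_desert_roi_summary.csv", package = "phenodesert")`.

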