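---
title: "Methods: low-amplitude phenocam phenology with phenodesert"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: low-amplitude phenocam phenology with phenodesert}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phenodesert)
```

# The problem

Fixed cameras photographing a vegetated scene several times a day provide a
cheap, high-resolution record of plant phenology. Each image pixel carries
8-bit red, green and blue digital numbers (DN), and the green chromatic
coordinate

$$\mathrm{GCC} = \frac{G_{DN}}{R_{DN} + G_{DN} + B_{DN}}$$

tracks canopy greenness through the season. In mesic systems the seasonal
GCC swing is large (0.1--0.2). In cold-desert shrublands and conifer
woodlands it is an order of magnitude smaller -- 0.016 to 0.062 GCC over
baselines near 0.31--0.33 in the communities this package emulates -- and
the signal competes with exposure noise, shadows, bare-soil background, and
ephemeral snow. phenodesert implements the full chain needed to date
phenophases in that low-amplitude regime, plus a synthetic-scene generator
with analytic ground truth so every stage is testable without field data.

# Chromatic extraction

ROIs are polygons over the frame; a pixel belongs to the mask when its
centre (0-based row/col integer coordinate, origin top-left) lies inside or
on the polygon boundary. Two ROI-averaging conventions exist in the
literature; they differ in dark scenes. The default is the **ratio of
means** -- chromatic coordinates of the per-channel mean DN -- which
down-weights dark pixels whose chromatic ratios are noisy;
mean-of-ratios is available via the `average` argument. Pixels with
$R+G+B=0$ carry no chromatic information: they are excluded and counted,
never clamped. By construction `gcc + rcc + bcc = 1` for every retained
sample, and chromatic coordinates are invariant to brightness scaling --
both properties are enforced by tests.

# The filter chain

Sub-daily series pass through three filters, in a fixed order that the
functions themselves enforce (night/snow, then spline, then max); running a
filter after a later stage is an error unless overridden.

**Night filter.** Samples with GCC strictly below 0.2 are dark, foggy or
badly white-balanced frames and are removed; a sample at exactly the
threshold is kept.

**Automated snow/night filter.** Snow (and the exposure flattening it
causes) produces a cluster of unreasonably low GCC values. Sorting GCC
ascending and plotting value against cumulative fraction, that cluster
appears as a steep initial ramp that breaks to the flatter, near-linear
lower range of the clean distribution. `snow_threshold_from_cdf()` fits a
piecewise-linear (segmented) regression to this curve by exhaustive least
squares, with BIC choosing between one, two and three segments. Two
safeguards matter in practice and are worth stating precisely:

* *Minimum segment size.* The first segment may be as small as 5% of the
  sample (`breakpoint_min_segment_fraction = 0.05`, floor of 4 samples).
  A larger trim would make snow fractions between 5% and the trim
  unrepresentable; tail stability is provided by the BIC penalty and the
  slope rule below, not by trimming.
* *Slope-ratio acceptance.* On sorted order statistics the residuals of a
  straight-line fit are strongly autocorrelated (Brownian-bridge-like), so
  a BIC computed under an iid-noise assumption will accept a spurious
  breakpoint on almost any sample -- including a perfectly uniform one.
  Worse, a *clean* seasonal series genuinely bends: the dormant-season
  cluster makes the lower CDF flat and the green season makes it steep,
  and a naive breakpoint there would put the threshold near the seasonal
  baseline and delete most of the data. Snow contamination has the
  opposite signature: a *sparse* low cluster, i.e. a first segment
  *steeper* than the second. A breakpoint is therefore accepted only when
  the first-segment slope is at least `slope_ratio_min = 2` times the
  second-segment slope. The factor 2 was calibrated on null simulations
  (uniform samples and clean seasonal series, 95th percentile of the null
  ratio about 1.3--1.8) against contaminated simulations (5th percentile
  about 2.5); it was fixed before, and independently of, the package's
  acceptance checks. The threshold returned is the midpoint of the two
  sorted values straddling the breakpoint of the two-segment fit -- the
  "first and second regression" -- with additional segments entering only
  model selection.

The variable filter then removes samples below
`max(0.2, threshold)`: the data-driven threshold augments the fixed night
filter and never relaxes it (`snow_floor = TRUE`, configurable). When no
breakpoint is supported the filter reduces exactly to the fixed filter.

**Spline filter.** A cubic smoothing spline (GCV-chosen smoothness,
optional `spline_spar_mult`) is fit to GCC over time; samples whose
residual is below $-k\,\hat\sigma$ ($k$ = `spline_outlier_sd` = 2) are
removed and the fit repeated (`spline_iterations` = 2). Only *downward*
outliers are removed: in camera greenness the artifacts -- shadow, weather,
exposure -- are drops, not spikes. If the spline is near-exact (residual SD
below $10^{-8}$) nothing is rejected.

**Max filter.** For each calendar day with at least one retained sample in
the centred 3-day window, the daily value is the 90th percentile of the
window's sub-daily GCC. Percentiles throughout the package use linear
interpolation between order statistics (R type 7); the convention matters
(the 90th percentile of three points differs across conventions) and is
fixed package-wide. Edge days use the truncated window. The companion
`moving_average_3day()` smooths daily environmental series with the same
centred window, averaging whatever values are present.

# The Gu double-logistic model

Filtered daily GCC is fit with the nine-parameter double logistic

$$y(t) = y_0 + \frac{a_1}{\left(1+e^{-(t-t_1)/b_1}\right)^{c_1}}
            - \frac{a_2}{\left(1+e^{-(t-t_2)/b_2}\right)^{c_2}}$$

with baseline $y_0$, recovery/senescence amplitudes $a_1, a_2$ (GCC),
inflection days $t_1, t_2$, rate scales $b_1, b_2$ (days) and shape
exponents $c_1, c_2$. Fitting is Levenberg--Marquardt least squares
(`minpack.lm::nls.lm`) from a data-driven start ($y_0$ at the 5th
percentile, amplitudes at the 5th--95th span, inflections at the first and
last midpoint crossings, $b = 10$, $c = 1$) plus five jittered restarts
under a fixed seed and two deterministic restarts that place the
senescence inflection well inside the span (when late-season data are
sparse -- e.g. snow-filtered -- jittered starts can all collapse onto an
optimum whose senescence lies beyond the data). The lowest-RSS solution
wins, except that among candidates within 1% of the best RSS --
statistically indistinguishable at these noise levels -- a fit that both
formally converged and has interior derivative extrema with the right
signs is preferred over one that did not. Box bounds keep the
optimizer out of unphysical corners: rate scales are capped at 60 days
(slower "transitions" are not seasonal transitions at these sites) and
inflection days may not leave the observed span by more than 60 days. A
fitted amplitude below $10^{-3}$ GCC flags the fit `degenerate` (e.g. a
constant series). On noiseless generator curves all nine parameters are
recovered to well under 1% relative error.

## Phenophase geometry

Four transition dates are defined by line intersections on the fitted
curve: tangents at the maximum and minimum of $dy/dt$ (the green-up and
senescence slopes), horizontal *baseline* and *max-line* at the curve
minimum and maximum over the data span, UD and SD where the recovery
tangent crosses baseline and max-line, a provisional DD where the
senescence tangent crosses the max-line, and RD at the baseline crossing.
GSL = RD − UD.

Semi-arid canopies commonly *green down* through the season, so the curve
leaves its maximum long before the true downturn and the max-line crossing
dates DD too early. A **plateau line** -- the least-squares line through
the fitted curve between SD and the provisional DD -- replaces the max-line
in the DD intersection. Because the senescence slope is negative and the
plateau line lies below the max-line, this adjustment moves DD *later*,
toward the real departure from the plateau trend. When the plateau is flat
(|slope| below $10^{-6}$ GCC/day) there is no greendown and no adjustment.
A single plateau pass is used (provisional DD from the max-line, one
refit). If a derivative extremum sits at the very edge of the span the
seasonality is flagged rather than extrapolated. For weak, noisy fits the
senescence extremum can precede the recovery extremum; the geometry is
still evaluated (yielding RD < UD and negative GSL) because that artifact
is exactly what the spatial histogram filter downstream is designed to
catch.

## Uncertainty

Residual resampling: each observation is perturbed by an independent draw
from a uniform distribution over the residual envelope
$[\min r_i, \max r_i]$ of the original fit, the model is refit
(warm-started at the original parameters), and phenophases are extracted;
1000 replications by default. Failed or non-seasonal replicates are dropped
and counted, and more than 20% drop is an error. Phenophase point estimates
and intervals are the median and 10th/90th percentiles of the ensemble;
GSL is summarized from the per-replicate RD − UD distribution, so its
median can legitimately differ from median RD minus median UD by a day --
the same effect visible in published summary tables. At daily noise of
0.003 GCC the 10th--90th UD interval covers the generator truth in roughly
90% of simulations (the package's acceptance script recomputes this).

# Per-pixel (spatiotemporal) analysis

Single-pixel trajectories are too noisy for the nine-parameter fit, so each
pixel gets a cubic smoothing spline (degrees of freedom $\approx n/8$,
bounded to $[6, 20]$) and the same line-intersection geometry applied to
the spline and its derivative. No uncertainty ensemble is computed per
pixel. Pixels are excluded -- never fatal -- when they have fewer than 20
daily values, the spline fails, no seasonal cycle exists, or the smoothed
amplitude is below `min_snr` = 1.5 times the pixel's own spline residual
SD. That last gate is deliberately conservative: it removes only pixels
whose apparent season is indistinguishable from their fit noise, while
leaving enough weak-noise pixels to reproduce the characteristic
negative-GSL artifact of bare interspace that the histogram filter exists
to remove. The histogram windows remain the primary classifier.

**Histogram filtering.** Per-pixel UD and RD histograms of a sparse scene
are bimodal: a vegetation bell plus scattered spurious dates from
interspace. Pixels with UD outside (50, 170) or RD outside (170, 330) --
defaults, configurable, with an automatic mode-±-2·MAD alternative -- are
classed `interspace`; the rest are `vegetation`. GSL is reported only for
vegetation pixels, and because the windows enforce RD ≥ 170 ≥ UD, no
negative GSL survives. On 20×20 generator scenes (vegetation amplitude
0.022 over flat interspace, noise 0.003) classification recovers ≥ 99% of
true labels across seeds.

**Interspace splitting.** Per-pixel seasonal GCC ranges (smoothed by
default; raw available) separate bare ground from woody material and
shadow. The values are sorted ascending (the empirical CDF ordering) and a
single changepoint in the mean is found by exhaustive within-segment SSE
minimization. Model selection needs care: on *sorted* data any split
reduces the SSE substantially (by ~3--4× even for unimodal samples), so an
SIC penalty alone always accepts. The split is therefore accepted only
when it reduces the SSE by at least `min_variance_ratio` = 8 -- above the
unimodal sorted-data reduction (normal ≈ 2.8, uniform ≈ 4) and far below
that of separated mixtures (> 50). The lower segment is bare ground, the
upper woody/shadow, each summarized by median and 10th--90th percentiles.

# The synthetic generator

`generate_gcc_series()` emulates the deployment the package targets: five
frames per day between 08:00 and 18:00, GCC following an analytic Gu curve
plus Gaussian noise (default SD 0.003 GCC). `gu_presets()` provides
parameter sets whose noiseless phenophases reproduce the date and
amplitude regimes of wet and mesic sedge meadows, sagebrush canopy, and
pinyon/juniper woodland in a Great Basin watershed (amplitudes
0.019--0.062, baselines 0.31--0.33, growing seasons 130--231 days).
`inject_snow()` replaces samples in given day spans with draws from a low
GCC band (0.20--0.27); `snow_scenario_spans()` freezes a benchmark winter:
ephemeral January--May pulses plus ~89% November--December cover with a
few clean anchor days, contaminating about a quarter of all samples.
`render_scene()` writes real PNG frames: each pixel's DN triple realizes
its class's chromatic trajectory at total brightness $R+G+B = 450$, so the
round-trip error through 8-bit quantization is at most $0.5/450$ per
coordinate; snow frames are bright (S = 600) and chromatically flattened
into the snow band. Ground-truth phenophases come from
`phenophase_truth()`, a dense-grid (0.01-day) finite-difference oracle that
shares no code with the fitting path.

What the generator does *not* emulate -- and what passing tests therefore
do not establish about field data -- includes camera shift and flicker,
lens flare, exposure drift, mixed pixels at canopy edges, partial/patchy
snow within a frame, and bimodal (monsoon) growing seasons. The interspace
of real scenes also carries scattered grasses with a weak true season;
where that signal is resolvable above noise it will, correctly, classify
as vegetation.

# Problem sizes and reproducibility

The test suite and the acceptance script run everything from scratch:
year-long series at 5 samples/day for the filter chain, 365-point daily
fits, 200-replicate ensembles over 50 simulation repeats for coverage,
20×20 scenes (400 spline fits) for classification, and 100 simulated
contamination series for snow-threshold power. These sizes were chosen to
give stable rates while keeping a full run in a few minutes on one core;
the uncertainty default in production use remains 1000 replications.
Every stochastic step takes an explicit seed, stage outputs carry the
configuration hash and seed in their headers, and reruns with equal
configuration are byte-identical.

# Known limitations

* One season per year: bimodal (monsoon) trajectories are out of scope.
* No image registration: camera shifts blur per-pixel trajectories.
* The snow filter assumes snow *depresses* GCC below the clean
  distribution; scenes whose baseline GCC sits at or below 1/3 with
  strongly blue-shifted snow may violate the separation it relies on.
* The slope-ratio and variance-ratio acceptance rules are calibrated
  constants, not significance tests; both are exposed as arguments.
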