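---
title: "Methods: record-shattering compound drought statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: record-shattering compound drought statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette is the package's own account of its statistical machinery: the
definitions it computes, the knobs that matter and their defaults, what the
synthetic-ensemble generator does and does not emulate, and the places where
a design choice had to be made.

## The problem

A drought that simultaneously covers several of the world's maize
breadbaskets — the USA, Brazil, Argentina, Europe, China and India — can put
an unprecedented fraction of the global maize area under water stress in a
single growing year. The question the package answers is probabilistic: in a
large ensemble of climate realizations, how likely is an annual **global
drought area** that does not merely break the previous record but *shatters*
it, and how much of that likelihood is created by long-term trends in the
mean and variability of surface soil moisture, region by region?

Single-model initial-condition large ensembles (SMILEs) make this tractable:
many realizations of one model under identical forcing differ only through
internal variability, so event counts across members estimate probabilities
that a single realization could never constrain.

## Definitions and pipeline

1. **Input**: annual surface soil moisture per (member, year, grid cell),
   conservatively regridded to a common lat-lon grid and annualized by
   calendar-year means (equal month weights by default; a day-weighting
   switch exists on `annual_mean()` — the annual-native synthetic pathway
   makes the equal-weight convention the natural default).
2. **Baseline** (`fit_baseline()`): per cell, the p-th percentile (default
   p = 20; p = 5 as restrictive variant) of the pooled members x 1850–1899
   sample, with the pooled mean and SD kept for standardized anomalies.
   The percentile estimator interpolates linearly between order statistics
   (`stats::quantile()` type 7) — continuous and reproducible; the `type`
   argument switches it. Classification is strictly below the threshold
   ("falls below"): ties count as non-drought.
3. **Drought area** (`drought_area()`): area-weighted percent of a scope's
   cells under drought, with cos-latitude weights (an equal-cell-weight
   switch exists, since "fraction of area" could also be read cell-wise).
   Regional series exist against both the regional and the global
   breadbasket denominator; with the global denominator the six regional
   series sum to the global one exactly.
4. **Records** (`record_events()`): within each member, the running maximum
   is tracked from the first year (1850), which is never itself an event —
   a previous record has to exist. A year is record-shattering when it
   exceeds the running maximum by at least the margin (default 5 percentage
   points of the scope's area, absolute, with `>=`); margin 0 gives ordinary
   record-breaking with a strict `>`. The running maximum updates on every
   exceedance, event or not. Records stay tracked from 1850 even when
   probabilities are reported for later windows.
5. **Probabilities**: `annual_probability()` counts events in a 31-year
   (±15) window and divides by 31 x n_members; by default only center years
   with a full window are reported, because the divisor is otherwise
   ambiguous — a truncated-window mode (divide by actual member-years)
   exists for display purposes at the series edges. `prob_at_least_one()`
   is the fraction of members with ≥ 1 event in an inclusive period.
   Multi-model aggregation is always: per-model ensemble statistic first,
   then the unweighted multi-model mean with the min–max inter-model range
   (`multimodel_summary()`).

## Detrending experiments

`pooled_moving_stats()` computes, per year and cell, the mean and sample SD
of the pooled members within a 31-year moving window. The three experiments
transform each value x(m, y, c) with μ_mov(y, c), σ_mov(y, c) and the pooled
preindustrial moments μ_ref(c), σ_ref(c):

* *detrend mean*: x − μ_mov + μ_ref — kills the mean trend, keeps the
  variability evolution;
* *detrend SD*: (x − μ_mov)/σ_mov · σ_ref + μ_mov — kills the variability
  trend, keeps the mean evolution;
* *detrend both*: (x − μ_mov)/σ_mov · σ_ref + μ_ref — stationary at
  preindustrial moments.

Design choices here:

* **Window edges are clipped** rather than dropped: near the series ends the
  window shrinks (to no less than 16 years), keeping the full 1850–2099
  span usable. `edges = "full"` restricts to complete windows for users who
  prefer that.
* **Thresholds are refit** on each transformed cube's own 1850–1899 pool.
  Since detrending pins that half-century to the preindustrial moments, the
  refit thresholds differ from the originals only by estimator noise; reuse
  of the original baseline is available (`refit_baseline = FALSE`).
* **Degenerate SDs fail loudly**: a pooled window SD at or below
  1e-12 · σ_ref raises an error naming the year and cell instead of
  silently inflating anomalies.
* The mean-preservation of *detrend SD* is exact only to first order
  (every year re-centers on its own window), which is why the tests allow a
  small tolerance there while the mean-cancellation test for noise-free
  linear input is exact.

`area_change_decomposition()` then reports Δ(mean drought area) between a
future period and 1850–1899 for the original data and each experiment: the
change surviving *detrend SD* is the mean-trend contribution, the change
surviving *detrend mean* the variability contribution, and *detrend both*
is the stationary control.

## Attribution and coincidence

`leave_one_region_undetrended()` splices the original series of one region
into the otherwise fully detrended cube (cells outside all regions are
untouched bit-exactly — they never enter area computations). A region's
contribution is the difference between the at-least-one probability of its
leave-one experiment and the detrend-all case; contributions are
deliberately *not* forced to add up to the total (record statistics are not
additive), and the tests only assert sign/magnitude patterns on constructed
ensembles.

`classify_global_events()` assigns each global record-shattering event-year
to exactly one category by the number of regions simultaneously flagged in
the same member-year — "0 regions", single-region categories (Europe/USA/
Brazil highlighted, "Rest only" for the others), "2 regions" … "6 regions" —
so fractions always sum to 100%. Flags are either regional record-shattering
events (regional-denominator series with a 5-point regional margin — the
convention chosen where the source material leaves the denominator open;
switchable) or **moderately extreme** droughts: the regional area strictly
exceeds the 80th percentile of that member's trailing years Y−30 … Y
(current year included in its own pool, exactly as defined). Global events
are drawn from 2000–2099 for sample size; the ±15-year
`windowed_association()` restricts to 2000–2085 so the full window fits.
With zero global events the classifier returns an explicit empty-result
status rather than NaN fractions.

## The synthetic-ensemble generator

`generate_smile()` draws

value(m, y, c) = μ₀(c) + trend(region(c), y) + s(region(c), y) · σ₀(c) · ε(m, y, c),

where ε is zero-mean unit-variance Gaussian noise with exponential spatial
correlation exp(−d/L) in great-circle degrees and AR(1) persistence in time
(applied before trend/scale injection, so detrending experiments face
realistic persistence; initialized from the stationary distribution).
Members are independent; per-member streams derive from the master seed by
a counter scheme, so enlarging the ensemble never reshuffles existing
members, and identical (config, seed) pairs are bit-identical.

Defaults, chosen once as plausible for annual surface soil moisture and kept
fixed: baseline mean 25 kg m⁻² and SD 1 kg m⁻² (typical mrsos magnitudes;
absolute units are immaterial because classification is percentile-based —
values are deliberately not floored at zero), AR(1) coefficient 0.3 and
correlation length 10° in the demo (soil-moisture memory and spatial scales
are not constrained by the source analysis — these are fixtures, not
claims). The demo scenario (`make_demo_fixture()`) uses a 12 x 24 grid
(15° cells), six box regions at realistic breadbasket latitudes, 20 members
per model, 1850–2099, and three synthetic "models" whose drying rates differ
by ±15% to create an inter-model range. Drying ramps start in 2000 in
Brazil, Europe and the USA, sized so end-of-century regional drought areas
land near 60/80/70% — the magnitudes reported for the strongly drying
breadbaskets — with mild SD inflation (x1.2) in Europe, a small wetting
trend in China, and no trends in Argentina and India.

What the generator does **not** emulate: model physics or forcing scenarios,
seasonality (its monthly mode exists only as equal-value months for
annualization tests), non-Gaussian tails, land-sea contrast, or
teleconnections between regions beyond the isotropic correlation field.
Passing tests therefore demonstrate the *statistical machinery* — threshold
calibration, record counting, detrending algebra, attribution logic — not
the realism of any particular climate projection.

## Numerical choices and degenerate inputs

* Sample (n−1) standard deviations throughout, including interannual
  variability diagnostics.
* Quantile type 7 everywhere a percentile is estimated (baseline, trailing
  moderate-drought rule), so the two stages are consistent.
* Longitudes normalized to [−180, 180); whole-longitude and date-line-
  crossing region boxes are handled explicitly.
* Conservative regridding works in sin-latitude x longitude measure, is
  linear, conserves the global area-weighted mean when the source tiles the
  destination, and regrids masks with a ≥ 50% area-overlap rule.
* Degenerate inputs fail with named locations: incomplete calendar years,
  zero pooled SDs under detrending, zero baseline SD on drought cells,
  constant time axes in trend fits.
* Evaluation diagnostics (1980–2009 baseline, 1980–2024 window) apply no
  detrending — they characterize raw drought-area behaviour — and the
  reference-band agreement helper is a pure predicate with no hidden
  tolerance.

## Problem sizes

The test-suite scenarios are sized for a laptop: the record-law check uses
200 members x 250 iid years; detrending recovery uses 30 members x 250
years x 60 cells (30 members keep pooled-moment estimator noise well below
the 2% recovery bound being verified); attribution recovery averages three
20-member demo-scale runs. The full demo analysis (3 models x 20 members x
288 cells x 250 years) completes in well under a minute.

## Known limitations

* Counting-based probabilities only — no extreme-value fitting, so tail
  estimates beyond the ensemble's sampling are out of reach by design.
* No harvested-area weighting: "maize area" is land area inside the region
  masks; a density-weighted variant would need external cropland data.
* No calendar-aware (360-day/noleap) time handling beyond pass-through, no
  growing-season windows, and no multi-layer soil moisture.
* Attribution uses the difference-from-detrend-all definition; interaction
  terms between regions are not allocated (no Shapley-style splitting).
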