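# shatterscan

Statistics of **record-shattering compound droughts** across the world's
major maize-producing regions, computed from single-model initial-condition
large ensembles (SMILEs) of annual surface soil moisture.

Simultaneous soil-moisture droughts across several breadbaskets can put a
record-shattering fraction of the global maize area under drought in a single
year — a class of event the food system is poorly adapted to. `shatterscan`
implements the full analysis chain needed to quantify that risk from gridded
ensemble data, plus a synthetic-ensemble generator so every stage can be
exercised and tested at desk scale without terabytes of climate model output.

## The statistics at the core

For each grid cell, a year is under **drought** when annual surface soil
moisture *x* falls below the cell's 20th percentile (5th for the restrictive
variant) of the pooled ensemble distribution over the preindustrial reference
period 1850–1899. The **drought area** of a scope *S* (one region, or the
union of all breadbaskets) in member *m* and year *y* is the area-weighted
cell fraction

&nbsp;&nbsp;&nbsp;&nbsp;A_S(m, y) = 100 · Σ_{c ∈ S, drought} w_c / Σ_{c ∈ D} w_c &nbsp;[%],

with cos-latitude weights *w_c* and denominator *D* either the scope itself
or the global breadbasket. A year is a **record-breaking** drought when
A(m, y) exceeds the member's running maximum, and **record-shattering** when
it exceeds it by at least a margin of 5 percentage points of the scope's
area (2.5/7.5 as sensitivity cases). Probabilities are counting-based:
a 31-year moving window gives the annual probability
p(y) = #events in [y−15, y+15] / (31 · n_members), and the multi-decadal
risk is the fraction of members with at least one event in a period
(2026–2055, 2026–2099).

Three **detrending experiments** pin the pooled 31-year moving-window mean
and/or standard deviation of soil moisture to preindustrial values
(x′ = (x − μ_mov)/σ_mov · σ_ref + μ_ref and its one-moment variants),
isolating the contributions of mean trends vs. variability changes.
Leave-one-region-undetrended experiments attribute the global risk to
individual regions, and coincidence tables classify each global event by how
many regions were simultaneously under regional record-shattering — or
**moderately extreme** (above the trailing 31-year 80th percentile) —
droughts.

## Worked example

```r
library(shatterscan)

config <- make_demo_fixture(seed = 42)   # 3 synthetic models x 20 members,
report <- run_full_analysis(config)      # 12 x 24 grid, 6 regions, 1850-2099
report
```

```
<shatter_report> 3 model(s)

P(at least one global record-shattering drought):
# A tibble: 4 × 6
  experiment   period     mean   min   max n_models
  <chr>        <chr>     <dbl> <dbl> <dbl>    <int>
1 detrend_both 2026-2055 0.05   0     0.15        3
2 detrend_both 2026-2099 0.1    0     0.15        3
3 original     2026-2055 0.45   0.35  0.55        3
4 original     2026-2099 0.933  0.85  1           3

Regional trend contributions (multi-model mean):
# A tibble: 12 × 5
   period    region    mean_contribution min_contribution max_contribution
 ...
 8 2026-2099 Brazil               0.217              0.15             0.3
 9 2026-2099 China               -0.05              -0.1              0
10 2026-2099 Europe               0.267              0.2              0.35
11 2026-2099 India                0                  0                0
12 2026-2099 USA                  0.4                0.3              0.5
```

Reading this: with the demo scenario's drying trends in Brazil, Europe and
the USA, 93% of ensemble members experience at least one global
record-shattering drought during 2026–2099 (inter-model range 85–100%),
versus 10% if soil moisture were stationary — the trends multiply the risk
roughly ninefold, and the leave-one-region experiments place essentially all
of that increase in the three drying regions (China's wetting trend even
dampens it slightly). The same report carries the drought-area
change decomposition, annual probability curves per experiment, coincidence
tables in both modes, the ±15-year windowed association, and evaluation
diagnostics (drought-area trends in %/decade and interannual σ over
1980–2024).

Every result is an ordinary tibble, so the pieces chain with the pipe:

```r
cube <- generate_smile(config$models[[1]])
base <- fit_baseline(cube, ref_period = c(1850, 1899), percentile = 20)
classify_drought(cube, base) |>
  drought_area(config$regions, scope = "global") |>
  record_events(margin = 5) |>
  prob_at_least_one(c(2026, 2099))
#> [1] 0.85
```

`plot_area_series()`, `plot_probability_curve()`, `plot_contributions()` and
`autoplot()` on coincidence tables give the standard diagnostic figures.

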