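---
title: "Nutrient mass balance for floating-plant invasions: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Nutrient mass balance for floating-plant invasions: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(floatload)
library(dplyr)
```

## The model

`floatload` treats a river catchment's annual nutrient export as the sum of
two stocks measured over the same year: the nutrient mass bound in the peak
standing crop of floating vegetation at a choke point, and the waterborne
load carried past the sampling point in surface water. The core assumption
is **annual trap-and-flush**: floating mats accumulate at a choke point
(dam, confluence backwater) through the growing season and are exported
essentially intact when rising flows flush them out, so the *peak* observed
cover is a proxy for the *annual* plant-bound export. This is conservative
in two directions — choke points are not perfectly efficient traps, and any
biomass exported before the peak is uncounted — so the plant share is best
read as a lower bound.

### Plant-bound pool

For a nutrient (N or P),

$$\mathrm{pool\ [Mg]} = A\,[\mathrm{km^2}] \times 10^6 \times
  B\,[\mathrm{kg\,m^{-2}}] \times c\,[-] \times 10^{-3}$$

where $A$ is peak vegetation cover, $B$ mean dry biomass per area and $c$
mean tissue nutrient content (dry-weight fraction). $B$ and $c$ are
*synthetic means*: cross-study literature syntheses computed by
`synthesize_traits()` as arithmetic means with the standard error of the
mean across studies. Tissue composition of water hyacinth varies widely
with the nutrient environment it grows through, which is why cross-study
spread — not analytical error — is the uncertainty that matters here.

### Waterborne load

$$\mathrm{load\ [Mg\,yr^{-1}]} = Q\,[\mathrm{m^3\,s^{-1}}]
  \times C\,[\mathrm{\mu g\,L^{-1}}] \times 0.031536$$

with $Q$ the mean annual discharge and $C$ the mean of the seasonal
digestible-nutrient samples. The constant is a 365-day year
(31,536,000 s yr⁻¹) times $10^{-9}$ Mg per (m³·µg L⁻¹); the year length is
fixed in `inst/extdata/defaults.yaml`. "Digestible" N and P are
peroxidisulfate-digested unfiltered samples — a conservative stand-in for
total N/P, since clay-bound particulate P can settle out before analysis;
the package labels concentrations accordingly and applies no correction.

### Sink fraction and uncertainty

$$\mathrm{sink\ [\%]} = 100\,\frac{\mathrm{pool}}{\mathrm{pool} +
  \mathrm{load}}$$

Uncertainty in the sink fraction is driven by the two trait syntheses.
`compound_envelope()` compounds their relative standard errors
multiplicatively,

$$\mathrm{pool}_{\pm} = \mathrm{pool} \times (1 \pm \mathrm{SE}_B/B)
  (1 \pm \mathrm{SE}_c/c),$$

and the envelope ends are pushed through the sink-fraction formula with the
load held fixed. Among the readings of "compounding the two standard
errors" we considered (literal product of absolute SEs, quadrature sum,
multiplicative factors), only the multiplicative-factor form yields the
asymmetric intervals that a ratio statistic requires and stays exactly
linear in each trait — so it is the one implemented. The tests cross-check
it against a 10⁵-draw Monte-Carlo propagation (independent normal draws on
both traits, mean ± 1 SD of the simulated fractions), which agrees with the
analytic envelope to within one percentage point for relative SEs up to
0.15; the analytic envelope is slightly wider, i.e. conservative.

### Mean versus median concentrations

Four seasonal samples per year make the mean concentration sensitive to a
single outlier. `sensitivity_mean_vs_median()` reports the sink-fraction
difference between mean- and median-based loads as an explicit sensitivity,
in percentage points. The mean remains the default everywhere; the median
is never substituted silently.

## Default parameters

| parameter | default | units | role |
|---|---|---|---|
| biomass per area $B$ | 2.0 (rel. SE 0.13, n = 15) | kg dw m⁻² | trait synthesis |
| P content $c_P$ | 0.004836 (rel. SE 0.076, n = 17) | dw fraction | trait synthesis |
| N content $c_N$ | 0.02391 (rel. SE 0.10, n = 14) | dw fraction | trait synthesis |
| year length | 31,536,000 | s | load integration |
| landcover threshold | 0.5 (strict >) | fraction | class membership |

The trait defaults are **calibrated synthetic stand-ins**, not a shipped
literature table: they are chosen so that $B \times c$ reproduces per-area
densities of 9.67 g P m⁻² and 47.8 g N m⁻² at full cover, the densities
implied by the Zambezi demo bundle's pools and areas, with study counts and
relative SEs typical of published trait syntheses for water hyacinth. Any
real analysis should replace them via `synthesize_traits()` on its own
records; the YAML config makes the defaults overridable without code.

## Supporting modules

**Rating curve.** `fit_rating_curve()` assumes $Q = aA^b$ and fits by OLS in
log–log space, reporting the log-space RMSE. The functional form and the
fitting space are package choices — regional curves are conventionally
power laws, and log-space residuals make the multiplicative gauge noise
homoscedastic. On noiseless synthetic stations the fit is exact to machine
precision; under lognormal noise ($\sigma = 0.2$, 20 stations) the mean
recovered exponent over 500 replicates is within ±0.05 of truth (log-log
OLS is unbiased for the exponent). Published discharges for the study's
small ungauged catchments are treated as printed inputs, not refit.

**Seasonality.** `composite_bimonthly()` uses calendar-aligned two-month
bins (Jan–Feb, …) and the per-bin **maximum** cover: peak biomass is the
export proxy, and the largest scene in a bin is the least cloud- and
timing-degraded view of the standing crop. `annual_peaks()` breaks ties
toward the earliest month and flags them, making `peak_month_histogram()`
deterministic. `monthly_climatology()` excludes missing months from
denominators rather than imputing. `period_stats()` summarises user-defined
multi-year regimes and counts (rather than silently drops) observations
outside every period.

**Vegetation geometry.** `full_coverage_area()` accepts a channel area
directly or a reach length × mean width (the Maramba demo reach: 0.087 km²
over 2.3 km implies a ~37.8 m mean width); `fringe_area()` models
bank-fringing vegetation as a constant-width strip (0.5 m × 1.2 km =
0.0006 km² in the demo).

**Landcover.** Grids are row-major with origin at the upper-left and pixel
centres at half-pixel offsets. A pixel belongs to a class when its fraction
**strictly exceeds** the threshold (default 50%), so exactly-0.5 pixels do
not count. `distance_to_nearest_urban()` is straight-line between pixel
centres; published distances of this kind may be along-stream or road
distances, so this quantity is documented as not independently auditable.

## The synthetic-data generators

Every input the pipeline consumes can be generated from a single
`scenario_config()` seed: lognormal trait records (positivity-preserving; a
generator choice, not a claim about real literature distributions),
log-uniform gauge networks with multiplicative lognormal discharge noise, a
Gaussian-bump annual cover cycle with a post-peak flush collapse, quarterly
concentration samples with probabilistic ×10 outliers, and blob-structured
fractional landcover. Generators restore the caller's RNG state and are
byte-identical for a fixed seed.

What they deliberately do **not** emulate: satellite-image classification
error and cloud gaps, serial correlation between quarterly samples,
correlated trait draws within studies, non-rectangular catchments, and any
plant growth kinetics. Passing the parameter-recovery tests therefore shows
the estimators are correct under the stated statistical structure, not that
the structure captures all features of real monitoring data.

The deterministic `zambezi_demo()` bundle carries the reference values for
the four Zambezi study catchments (peak vegetation areas 5.5, 0.006, 0 and
0.087 km²; discharges 989, 11.4, 1.9, 1.9 m³ s⁻¹; annual mean digestible
P/N concentrations 7.3/289, 15.6/333, 14.1/642, 32.4/718 µg L⁻¹; and the
catchment landcover areas), so one `nutrient_budget()` call regenerates the
per-catchment loads, pools and sink fractions end to end:

```{r demo}
demo <- zambezi_demo()
budget <- nutrient_budget(demo$vegetation, demo$concentrations,
                          demo$discharge)
select(as_tibble(budget), site, nutrient, pool_Mg, load_Mg_yr,
       sink_pct, sink_lo_pct, sink_hi_pct)
```

## Numerical choices and degenerate inputs

- Internal computation is full precision; rounding to printed precision is
  left to report formatting.
- A site with no vegetation rows has a zero pool and a zero sink fraction
  with a degenerate (point) envelope; a zero-pool, zero-load pair is an
  explicit error rather than 0/0.
- Single-study trait syntheses report SE = 0 with a warning and a
  `se_degenerate` flag rather than NA.
- Relative SEs are validated to [0, 1): at 1 the lower envelope would hit
  zero and the interval lose meaning.
- Rating curves refuse fewer than two stations or a zero range of areas;
  predictions refuse non-positive areas.
- Test and acceptance problem sizes — 10⁵ Monte-Carlo draws, 500 rating
  replicates of 20 stations, 20-year cover series — were chosen as the
  smallest sizes at which the sampling noise of each check is comfortably
  below its tolerance.

## Known limitations

- The trap-and-flush assumption makes every plant share a lower bound; no
  trapping-efficiency correction is attempted.
- Digestible P may under-measure total P where clay particulates are
  significant; no correction is modelled.
- The budget is an annual stock comparison: no growth kinetics, uptake
  rates or within-year nutrient dynamics.
- Four samples per year is sparse; the mean-vs-median sensitivity is
  reported but cannot substitute for denser sampling.
- The rating curve transfers a regional area–discharge scaling to ungauged
  basins; it carries that regionalisation's usual biases for strongly
  regulated or karstic catchments.
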