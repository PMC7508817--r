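# floatload

Mass-balance analysis of nutrients bound in invasive floating-plant biomass
versus nutrients carried in river surface water.

## The problem

Free-floating macrophytes such as water hyacinth (*Eichhornia crassipes*)
bloom in nutrient-polluted tropical rivers, accumulate seasonally at choke
points (dams, confluence backwaters) and are flushed downstream when flows
rise. Because the plants assimilate N and P directly from surface water,
the standing crop at a choke point is itself a nutrient pool — and if the
seasonal flush exports it, an annual nutrient flux. `floatload` quantifies
how large that plant-bound flux is relative to the conventional waterborne
export of a catchment.

For each catchment the package computes:

- **Plant-bound pool** (Mg): peak vegetation cover area × synthetic mean dry
  biomass per area × synthetic mean tissue nutrient content, where the
  "synthetic means" are literature syntheses with standard errors,

  `pool = A [km²] × 10⁶ × B [kg m⁻²] × c [–] × 10⁻³`

- **Waterborne load** (Mg yr⁻¹): mean annual discharge × mean digestible
  nutrient concentration,

  `load = Q [m³ s⁻¹] × C [µg L⁻¹] × 0.031536`

- **Plant sink fraction** (%): the plant share of total annual export,

  `sink = 100 · pool / (pool + load)`

  with a confidence interval from the compounded relative standard errors of
  the two trait syntheses: `pool · (1 ± SE_B/B)(1 ± SE_c/c)`.

Supporting modules fit power-law area–discharge rating curves for ungauged
tributaries (`Q = a·Aᵇ`, log–log OLS), summarise vegetation-cover and
hydrograph seasonality (bimonthly compositing, annual peaks, peak-month
histograms, multi-year period statistics), threshold fractional-landcover
grids into per-catchment class areas, and generate seeded synthetic inputs
for every stage.

## Worked example

The packaged demo bundle carries reference inputs for four Zambezi
tributaries in southern Zambia (Kafue below Itezhi-Tezhi, Chongwe, Little
Chongwe, Maramba):

```r
library(floatload)

demo <- zambezi_demo()
budget <- nutrient_budget(demo$vegetation, demo$concentrations, demo$discharge)
print(as.data.frame(budget), digits = 4)
#>             site nutrient veg_area_km2   pool_Mg pool_lo_Mg pool_hi_Mg q_m3s
#> 1        chongwe        N        0.006   0.28692    0.22466    0.35664  11.4
#> 2        chongwe        P        0.006   0.05803    0.04665    0.07056  11.4
#> 3          kafue        N        5.500 263.01000  205.93683  326.92143 989.0
#> 4          kafue        P        5.500  53.19600   42.76320   64.67995 989.0
#> 5 little_chongwe        N        0.000   0.00000    0.00000    0.00000   1.9
#> 6 little_chongwe        P        0.000   0.00000    0.00000    0.00000   1.9
#> 7        maramba        N        0.087   4.16034    3.25755    5.17130   1.9
#> 8        maramba        P        0.087   0.84146    0.67644    1.02312   1.9
#>   conc_ugL load_Mg_yr sink_pct sink_lo_pct sink_hi_pct
#> 1    333.0   119.7170   0.2391      0.1873       0.297
#> 2     15.6     5.6084   1.0241      0.8249       1.242
#> 3    289.0  9013.6511   2.8352      2.2337       3.500
#> 4      7.3   227.6805 18.9393     15.8122      22.123
#> 5    642.0    38.4676   0.0000      0.0000       0.000
#> 6     14.1     0.8448   0.0000      0.0000       0.000
#> 7    718.0    43.0214   8.8177      7.0389      10.730
#> 8     32.4     1.9414 30.2378     25.8399      34.513
```

Reading the Kafue P row: 5.5 km² of peak floating vegetation binds ~53 Mg of
phosphorus, against a waterborne export of ~228 Mg yr⁻¹ — so the plants
account for ~19 % (CI 15.8–22.1 %) of the catchment's total annual
digestible-P export. In the highly urbanized Maramba catchment the plant
share of P reaches ~30 %; in the Little Chongwe, where no floating
vegetation was observed, it is zero.

`autoplot(budget)` draws the stacked plant-vs-water shares;
`tidy()`/`glance()`/`autoplot()` work on rating-curve fits:

```r
curve <- fit_rating_curve(gen_gauges(scenario_config(seed = 1)))
tidy(curve)
#> # A tibble: 2 × 2
#>   term       estimate
#>   <chr>         <dbl>
#> 1 coef_a      0.00953
#> 2 exponent_b  0.909
predict_discharge(curve, 510)
#> [1] 2.751725
```

A thin command-line wrapper over the same functions ships in
`inst/cli/floatload.R` (subcommands `budget`, `rating`, `season`, `veg`,
`landcover`, `simulate`, `demo-zambezi`, `report`).

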