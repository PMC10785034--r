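# aqhia — scenario-based air quality exposure and health impact assessment

`aqhia` is an R package for the analysis chain that turns an anthropogenic
emission perturbation — a lockdown, a control policy, a fuel-use shift —
into estimates of ambient exposure change and premature mortality over a
gridded domain. It is written for air-quality and environmental-health
analysts who have (or can emulate) paired chemical-transport-model runs and
need the accounting around them to be explicit, reproducible and tested:

* **Synthetic scenario generation** — paired hourly ozone / daily PM2.5
  fields with controllable ground truth (shared meteorological noise across
  scenarios, deterministic emission signal), clustered population, county-
  blocked baseline mortality, lockdown-shaped activity series, and
  satellite-style retrieval scenes.
* **Emission accounting** — monthly activity scaling of sectoral
  inventories and mass-weighted fractional-change tables by species, sector,
  month and state, with state percentile bands.
* **Exposure metrics** — regulatory-style MDA8 ozone (all 24 start hours,
  windows crossing midnight, 6-of-8 and 13-window completeness rules),
  annual 4th-highest and period means, population weighting, monitor-site
  sampling, FNR ozone-regime classification, and exact paired-run
  attribution of changes to emissions versus meteorology.
* **Health impact assessment** — the log-linear concentration–response
  model with TMREL clamping and CI propagation by RR-endpoint substitution.
* **Satellite comparison** — pixel filtering, model-consistent air-mass-
  factor recalculation (slant-column preserving), source-region
  classification, and orthogonal distance regression.

## The model at the core

Attributable deaths per grid cell:

    Deaths = P × BR × (1 − exp(−β·ΔX)),   β = ln(RR) / Δq,
    ΔX = max(0, X − TMREL)

with `P` population, `BR` baseline annual all-cause mortality rate, `X` the
annual exposure metric (annual-mean MDA8 O₃ in ppb; annual-mean 24-h PM2.5
in µg m⁻³), and `RR` the relative risk per increment `Δq`. Defaults:
RR = 1.02 (1.01–1.04) per 10 ppb O₃ with TMREL 26.7 ppb, and RR = 1.06
(1.04–1.08) per 10 µg m⁻³ PM2.5 with TMREL 2.8 µg m⁻³. Scenario pairs are
differenced cell-wise; averted totals are also reported as an integer
percent of the reference burden.

## Worked example

```r
library(aqhia)

cfg <- default_config(seed = 1, n_lat = 8, n_lon = 10, n_days = 60)
b <- run_pipeline(cfg)
print(b$summary, digits = 3)
#>                        quantity     value
#> 1        nox_change_apr_jun_pct -2.11e+01
#> 2        voc_change_apr_jun_pct -1.86e+01
#> 3     o3_pw_emission_change_ppb -8.88e-01
#> 4  pm25_pw_emission_change_ugm3 -6.49e-01
#> 5                 o3_deaths_bau  9.96e+04
#> 6                 o3_deaths_cov  9.41e+04
#> 7             o3_deaths_averted  5.51e+03
#> 8            o3_averted_percent  6.00e+00
#> 9               pm25_deaths_bau  1.07e+05
#> 10              pm25_deaths_cov  9.64e+04
#> 11          pm25_deaths_averted  1.10e+04
#> 12         pm25_averted_percent  1.00e+01
#> 13         urban_no2_change_pct -1.52e+01
#> 14                    odr_slope  1.03e+00
```

Reading the output: the lockdown-shaped activity profiles cut April–June
NOx emissions by 21% and VOC by 19% relative to business as usual; holding
meteorology fixed, those cuts lower population-weighted 4th-highest MDA8
ozone by 0.89 ppb and mean PM2.5 by 0.65 µg m⁻³ over this (short,
60-day) record; run through the concentration–response model they avert
5,510 of 99,600 ozone-attributable deaths (6%) and 11,000 of 107,000
PM2.5-attributable deaths (10%) per year at this synthetic domain's
population. The satellite stage sees urban NO2 columns fall by 15%, with
an ODR slope of 1.03 between true model columns and the AMF-adjusted
noisy pixels. CI propagation is available per pollutant:

```r
summarize_deaths(b$hia$o3$bau)
#> O3 deaths BAU: 99629 (95% CI 50488-194061)
```

A full-year run (`default_config(seed = 1)`, 40 × 60 grid, 365 days) takes
about a minute; annual numbers are smaller than the 60-day ones above
because the activity dip rebounds over the year.

There is also a thin command-line wrapper over the same functions:

```sh
Rscript inst/cli/aqhia.R run --config inst/extdata/demo_config.yaml --out out/
Rscript inst/cli/aqhia.R report --out out/
```

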