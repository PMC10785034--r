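---
title: "Methods: from emission perturbations to attributable mortality"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from emission perturbations to attributable mortality}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aqhia)
```

# Overview

`aqhia` implements the analysis chain that sits downstream of a chemical
transport model when assessing how an anthropogenic emission perturbation —
for instance, the activity collapse during pandemic lockdowns — translates
into ambient ozone and PM2.5 exposure and, through a log-linear
concentration–response function, into premature mortality. The chemistry and
transport themselves are deliberately out of scope: the package generates
synthetic gridded concentration fields with controllable ground truth, so
every downstream operator (exposure metrics, attribution, health impact
assessment, satellite-style column comparison) can be tested offline and
end to end.

# The health impact model

Attributable deaths in each grid cell follow

$$\mathrm{Deaths} = P \times BR \times \left(1 - e^{-\beta \, \Delta X}\right),$$

where $P$ is the cell population, $BR$ the baseline annual all-cause
mortality rate, and $\Delta X = \max(0, X - \mathrm{TMREL})$ the annual
exposure metric above the theoretical minimum-risk exposure level. The slope
is $\beta = \ln(RR)/\Delta q$ for a relative risk $RR$ quoted per increment
$\Delta q$; with this form the attributable fraction at an excess of exactly
one increment is $1 - 1/RR$. The default risk table uses cohort-style
all-cause estimates: $RR = 1.02$ (95% CI 1.01–1.04) per 10 ppb ozone with a
26.7 ppb TMREL, and $RR = 1.06$ (95% CI 1.04–1.08) per 10 µg m⁻³ PM2.5 with
a 2.8 µg m⁻³ TMREL.

Three choices here were genuinely open and are worth stating:

* **The slope formula.** A form like $\beta=\ln(RR/\Delta X)$ occasionally
  appears in print but is dimensionally inconsistent (the argument of the
  logarithm would carry units, and $\beta$ would not scale with the quoted
  increment). `beta_from_rr()` therefore implements the standard log-linear
  form $\ln(RR)/\Delta q$, which reproduces the defining property
  $1-e^{-\beta\Delta q} = 1 - 1/RR$ exactly.
* **Clamping after aggregation.** $\Delta X$ is computed from the *annual*
  metric (annual mean MDA8 for ozone, annual mean 24-h PM2.5) and then
  clamped at the TMREL — not clamped day by day. Daily clamping would
  double-count the threshold for series that straddle it.
* **CI propagation.** Confidence intervals substitute the RR interval
  endpoints and recompute the whole chain (`hia_run()` returns all three
  surfaces). No Monte Carlo over population or baseline rates is attempted,
  matching how such intervals are conventionally reported; the CI therefore
  reflects concentration–response uncertainty only.

Cells with zero population contribute zero deaths and report a zero rate
per 10⁵ people. Scenario comparisons (`averted()`) difference the reference
and perturbed death surfaces cell-wise and report the total also as an
integer percent of the reference burden — the convention behind headline
"X% of attributable deaths could be averted" figures.

# Exposure metrics

**MDA8.** The daily maximum 8-hour average is named far more often than it
is defined, so the package fixes a deterministic convention: candidate
8-hour windows start at every hour 0–23 of the local day and may extend
into the next day; a window is valid with at least 6 of 8 hourly values
(the mean is over the present values); the day's MDA8 is the maximum over
valid windows; and a day is reported only when at least 13 windows are
valid. This follows the long-standing regulatory computation; the newer
7:00–23:00 start-hour variant is available via
`mda8_daily(start_hours = "7to23")`. The implementation accumulates window
sums in chronological order with extended precision, so it is bit-identical
to a naive `sum(values)/count` window scan — the property the test suite
verifies exhaustively against a brute-force oracle.

**Order statistics and means.** `annual_nth_highest()` (with $n=4$, the
basis of the US ozone design value) keeps duplicates and descends the
sorted daily values; cells with fewer than $n$ valid days are missing with
a warning. `period_mean()` requires 75% coverage of the averaging window;
below that the cell is missing, never extrapolated.

**Population weighting.** `population_weighted()` reports
$\sum p_i x_i / \sum p_i$ together with *both* the population-weighted and
the unweighted standard deviation across cells, since either convention is
found in practice and the choice is rarely stated.

**Attribution.** The paired-run design makes attribution an exact
telescoping identity rather than a regression: with surfaces for
(met A, BAU), (met B, BAU) and (met B, perturbed),
`attribute_change()` returns the emission effect (difference at fixed
meteorology), the meteorology effect (difference at fixed emissions), and
their sum, which equals the total change to machine precision. The pivot is
fixed at (met B, BAU) so the decomposition has zero interaction residual.

**FNR.** The formaldehyde-to-NO2 column ratio uses the ratio of period
means, not the mean of instantaneous ratios (the two differ for any
non-constant series; a two-time counterexample is in the tests).
`classify_regime()` uses inclusive transition bounds, e.g. 4.1–5.0.

# The synthetic generator

The generator emulates the statistical structure of the real inputs, not
their physics:

* **Hourly ozone** = background + seasonal cosine (peak near calendar day
  201) + diurnal sine (peak near 15:00 local) + a smooth, fixed spatial
  anthropogenic enhancement scaled by $(1-\text{monthly reduction})$ +
  stationary AR(1) noise, clipped at zero. The noise stream is seeded by
  (seed, meteorology-year label) only and the emission term is purely
  deterministic, so a scenario pair sharing its meteorology differs exactly
  by the injected emission signal — the property that makes paired-run
  attribution exact and parameter recovery testable.
* **Daily PM2.5** is log-normal (default median 8 µg m⁻³, GSD 1.6), with
  the monthly reductions applied to an anthropogenic share of 0.35. That
  share was chosen once so that a lockdown-shaped reduction produces an
  annual population-weighted PM2.5 response of a few percent — the scale at
  which emission-driven PM2.5 changes sit relative to ozone in this kind of
  assessment, reflecting the large secondary and non-anthropogenic
  contributions to PM2.5 mass.
* **Activity series** dip to $1-\text{depth}$ at the trough month with a
  half-depth shoulder the month before and an exponential rebound; the
  default profiles put a 40% April gasoline trough at the centre of the
  lockdown signal, consistent with the observed collapse in fuel sales.
* **Population** decays with squared distance from random urban centres
  with log-normal dispersion, normalised to a national total; **baseline
  mortality** is drawn once per axis-aligned rectangular county block from
  a truncated normal, constant within the county — preserving the
  county-to-grid rasterisation structure of real rate tables.
* **Satellite scenes** carry layered a priori profiles (exponential decay
  over ~3 layers), scattering weights increasing with altitude, an original
  AMF self-consistent with the two, multiplicative column noise, and
  quality fields for filtering.

What the generator does *not* emulate: chemistry (no nonlinear ozone
response to precursor changes — the enhancement scales linearly with
activity), transport (no spatial error correlation beyond the smooth
enhancement pattern), stratospheric contributions, retrieval slant-column
errors, or fires. Passing tests therefore demonstrate the correctness of
the accounting and statistics, not fidelity to any particular year of real
atmosphere. The spatial autocorrelation of met-driven anomalies is not
constrained by the emulated study at all, so it is left as a parameter
(`ar1_rho` controls only temporal correlation; cells are independent).

# Emissions accounting

Fractional changes are **mass-weighted aggregates**
($\sum \mathrm{scaled}/\sum \mathrm{reference} - 1$), never averages of
fractions, at national, sector and state level; group reference masses are
carried in the change table so period aggregates stay mass-weighted.
Percentile bands across states interpolate linearly between closest order
statistics (`quantile(type = 7)`) — a rule that must be fixed explicitly
because figure captions never state one. The period spread is one standard
deviation of state-level pooled fractions with states weighted equally by
default (`weight_states_by_mass = TRUE` switches to mass weighting; a
single state reports zero spread by convention). Sectors without activity
data — agricultural ammonia, fugitive dust — must be *declared* unscaled
rather than silently passed through.

# Satellite comparison

Model-to-retrieval comparison recomputes each pixel's air-mass factor from
the model profile, $\mathrm{AMF}_m = \sum_l s_l m_l / \sum_l m_l$ over
tropospheric layers, and adjusts the vertical column by
$\mathrm{AMF}_{orig}/\mathrm{AMF}_m$, preserving the implied slant column
exactly. The scattering-weight and shape-factor pathways are deliberately
unified — both reduce to the same weighted-mean formula. Default pixel
filters (qa ≥ 0.75, cloud fraction ≤ 0.3, SZA ≤ 70°) follow common L2
user-guide practice and are configuration-exposed. Source regions are
labelled by the sector contributing at least 60% (inclusive) of
business-as-usual NOx emissions; above 0.5 the label is necessarily
unique. Scatter comparisons use orthogonal distance regression, computed
from the principal axis of the centred covariance matrix (both axes carry
comparable error, so ordinary least squares would bias the slope toward
zero); the slope CI is a jackknife variance estimate with normal
quantiles — a stated large-sample choice, since no canonical small-sample
CI exists for the orthogonal slope.

# Numerical choices and degenerate inputs

* All generators are bit-reproducible: streams are derived from
  (seed, purpose-label) hashes below $2^{31}$, and RNG state is restored
  after each call.
* Concentrations are clipped at zero; clipping is the one operation that
  can break exact scenario separability, and it only engages when the
  deterministic part minus noise excursions reaches zero.
* Missing data propagate, never extrapolate: windows below completeness
  thresholds are invalid, cells below coverage are missing, missing cells
  contribute zero deaths.
* Degenerate guards: fewer than 2 states for a percentile band, empty
  month sets, zero reference masses, zero-population masks, identical
  points in ODR, tropopause indices out of range, and perturbed scenarios
  without a BAU partner are all hard errors naming the offending input.
* Calendar: a 365-day non-leap year in local standard time (MDA8 windows
  are defined in local time); the record may start at any month, and an
  April start matches an April-to-March assessment window.

# Problem sizes

The default configuration runs a 40 × 60 cell grid for 365 days — large
enough that annual order statistics, county blocking and population
clustering all behave realistically, while a full pipeline run stays
around a minute on a single core. The test suite uses smaller grids
(typically 4 × 5 to 6 × 8) and shorter records for operator-level checks,
and full 365-day records wherever an annual metric is the object under
test, e.g. the 20-seed emission-signal recovery study.

# Known limitations

* Linear emission-to-concentration response: the generator cannot produce
  NOx-titration effects (urban ozone *increases* under NOx cuts) that real
  VOC-limited chemistry shows; regime classification via FNR is provided,
  but the synthetic fields will not exhibit the regime shift itself.
* County blocks are rectangles, population centres are isotropic, and the
  enhancement pattern is fixed; none of the three reproduces real spatial
  covariance between exposure, population and baseline rates, which is
  exactly the covariance that drives real attributable-death totals.
* The HIA is all-cause, two-pollutant, and additive; no age stratification,
  cause-specific rates, nonlinear exposure–response shapes, or morbidity.
* File I/O uses self-describing CSV with full-precision numerics rather
  than NetCDF containers; the formats are exact round-trip but not
  CF-toolchain-compatible.
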