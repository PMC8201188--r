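---
title: "Hourly land use regression for PM2.5: models, choices and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hourly land use regression for PM2.5: models, choices and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

`pmlur` fits, per time slot, the linear exposure model

$$y_i = \beta_0 + \sum_j \beta_j x_{ij} + \alpha_i,
  \qquad \alpha_i \sim N(0, \sigma^2),$$

where $y_i$ is the PM2.5 concentration at monitoring station $i$
(μg·m⁻³) and the $x_{ij}$ are geographic covariates of the station's
surroundings. A *slot* is one of the twelve combinations of season
(heating / non-heating), day type (working / non-working) and hour
(0:00, 8:00, 18:00). Fitting each slot separately is what gives the
model its temporal resolution: the same station can have a different
POI term at midnight than at the morning rush, reflecting where people
actually are at that hour.

The model is estimated by ordinary least squares after a supervised
variable selection (below). It assumes linearity in the covariates,
independent homoscedastic errors across stations, and that the
buffer-aggregated geography is an adequate proxy for local emission and
dispersion processes. None of these assumptions is innocuous — they are
the standard LUR trade-off of interpretability and data economy against
physical fidelity.

## The predictor schema

Buffered predictors are aggregated over circular neighbourhoods of
radius 300–3000 m (twelve radii). For each radius the package computes

* land-use **areas** (m²) for seven classes: arable, garden, woodland,
  grassland, commercial service, industrial/mining-warehousing,
  residential — the intersection area of the class's polygons with the
  closed disk;
* road **lengths** (m) for primary and secondary roads — road length
  substitutes for unavailable traffic-flow data, a standard and
  well-validated proxy;
* POI **counts** for thirteen categories, plus industrial point
  sources.

Elevation and population are point-sampled from rasters; the four
meteorological covariates are interpolated from the met-station network
to each target by ordinary kriging, so "temperature at a station" always
means *kriged* temperature — the same quantity the mapping stage later
uses on the grid. The full matrix has
$12 \times (7 + 2 + 13 + 1) + 6 = 282$ columns.

Choices worth making explicit:

* **Boundary inclusive** (distance ≤ r). This makes every buffered value
  exactly nondecreasing in the radius, a property the test suite asserts.
* **Circles are 256-gons** for polygon intersections. The relative area
  error is ≈ 1e-4, an order of magnitude below every tolerance used.
  Intersections are computed by Sutherland–Hodgman clipping; for slivers
  where a disk grazes a polygon corner the absolute error of the
  approximation (~1e-4 · πr²) can exceed the sliver itself, which is why
  oracle comparisons are made at substantial disk coverage.
* **Population is point-sampled, industry is buffered.** The schema
  treats population like elevation (a raster attribute of the site) and
  industrial sources like POIs (countable emitters). Published hourly
  models report unbuffered population/elevation terms, which this
  layout reproduces.
* **The 3000 m radius** extends the classical 300–2500 m ladder because
  published hourly models retain `_3000` variables; the schema would be
  unable to represent them otherwise.

## Variable selection

With 282 candidates and a few dozen stations, unconstrained regression
is hopeless; the package implements the two-stage supervised procedure
standard in this literature.

**Screening.** For each base variable the buffer radius with the highest
absolute Spearman correlation against the response is retained and the
other radii are discarded (ties go to the smallest radius; mid-ranks for
ties in the data; a configurable `min_abs_rho` floor, default 0, can
drop weakly correlated variables entirely). This controls the extreme
collinearity *within* a variable's radius ladder. "Category" is read as
*base variable* (e.g. catering across its radii), not "all POIs": final
published models contain several POI types simultaneously, which the
broader reading would forbid.

**Stepwise regression.** Forward entry adds, at each step, the candidate
with the smallest entry p-value (the t-test of its coefficient in the
augmented model) if that p-value is below 0.05; a backward pass then
removes any term whose p-value has risen to 0.05 or above; finally a VIF
pass removes the highest-VIF term while any VIF ≥ 5 and bars it from
re-entry. The loop repeats to a fixed point. Whether the published
procedure was forward-only or bidirectional is not stated anywhere we
know of; forward + backward + VIF is the defensible superset and is
deterministic. Entry stops early when the residual sum of squares is
numerically zero, so perfect fits terminate cleanly.

**Sequential partial R².** The per-term "partial R²" is implemented as
the entry-order increment $R^2_{(1..j)} - R^2_{(1..j-1)}$. The published
tables this layout mirrors have per-term partials that sum *exactly* to
the printed model R² (e.g. 0.867 + 0.073 + 0.015 = 0.955), which holds
for sequential increments but not for squared semipartials; the package
asserts the additivity identity to 1e-9 on every fit.

## Kriging

Ordinary kriging is used twice — meteorology to stations/grid, and
smoothing of the mapped surface. The engine fits a variogram
(spherical by default; exponential and gaussian available) to the
binned empirical semivariogram by pair-count-weighted least squares from
a small deterministic grid of starting points, then solves the
unit-sum-constrained kriging system once per prediction batch. Numerical
conventions: $\gamma(0) = 0$ even with a nugget (so zero-nugget kriging
interpolates exactly); duplicate sample coordinates are averaged before
solving; a curve already at its sill before the first observed lag is
collapsed to pure nugget (the two are indistinguishable on such data);
an all-zero empirical variogram yields a nugget-only model with a
warning. For the exponential family the range parameter is the
e-folding length, matching the synthetic generator's
$\mathrm{cov}(h) = \sigma^2 e^{-h/\lambda}$.

Meteorology is interpolated per slot by default. An `annual`-style
pooled mode (`met_aggregation = "annual"`) is provided because some
descriptions of the approach average meteorology across the year, but a
pooled field is internally inconsistent with hour-specific models whose
tables contain slot meteorology; slot-specific is the self-consistent
default.

## Validation

**Cross-validation** is 10-fold with a seeded equal-size partition
(sizes differ by at most one). By default the selected term set is held
fixed and only the coefficients are refit per fold — matching the usual
presentation of one final model per slot with accompanying CV metrics —
and the pooled CV R² is $1 - SSE_{held}/SST$ over all held-out
predictions jointly, then adjusted with the full $n$ and the model's
$p$ (no published definition of the pooling exists; this one is fixed
and documented). `reselect = TRUE` re-runs the entire selection inside
every fold for an honest-CV comparison. Within-fold aliased columns are
dropped with a zero coefficient rather than failing the fold.

**Slot comparisons** between hours use a normality gate: Shapiro–Wilk on
both samples at α = 0.05 routes to a two-sample t-test (Welch by
default, as the safer choice; pooled Student available) or a two-sided
Mann–Whitney U. The tests are unpaired, mirroring the naming of
Mann–Whitney in this literature, although station-matched pairing would
also be defensible. Descriptive summaries use linear-interpolation
quantiles (R type 7).

## Regression mapping

The fitted equation is evaluated at the centers of a 3 km grid anchored
at the extent's lower-left corner (grid registration is otherwise
arbitrary; a single midpoint cell is used when the extent is smaller
than the spacing). Only the model's own terms are extracted at the grid
points, which keeps mapping cheap. Negative predictions are clamped to
0 μg·m⁻³ and *counted*, so silent distortion is visible; with
nonnegative predictors and coefficients the counter stays at zero. The
grid predictions are kriged to a finer raster (default 500 m when called
directly; the pipeline uses 2 km, purely presentational) —
`force_zero_nugget = TRUE` makes the surface an exact interpolator of
the deterministic regression values. The station-level relative error is
defined as $100(\bar{\hat y} - \bar y)/\bar y$; published relative-error
percentages for this quantity cannot be reconciled with the
corresponding published means under any simple definition, so no fixture
asserts them.

## The synthetic city

The generator is the package's ground-truth instrument, not a fixture:
35 monitoring stations (clustered towards the urban core) and 33 met
stations on a 100 km × 100 km planar extent; POIs as inhomogeneous
Poisson processes with intensity $\propto e^{-d/\lambda}$ from the
center (per-category mean counts of order 10³–10⁴, λ = 15 km),
reproducing urban-core clustering; a deterministic seeded ring + radial
primary-road skeleton with short secondary connectors; a Voronoi mosaic
over class-labelled seeds for land use (urban classes center-biased),
which tiles the extent exactly with convex cells; elevation as a
northwest-high/southeast-low gradient plus smooth bumps; population
decaying from the center; meteorology as Gaussian random fields with
exponential covariance and season/hour-specific means. Observations are
drawn from a per-slot sparse linear truth (support ≤ 6 variables) with
Gaussian noise; negative draws are floored at 0.1 μg·m⁻³ and flagged
(flooring keeps the noise analyzable; resampling would bias it);
missingness removes ⌊rate·n⌋ stations. One global seed is split into
named substreams (city / met / obs) so adding a stage never shifts
another stage's draws, and all outputs are bit-reproducible.

The default truth embeds the seasonal contrast seen in real hourly
models — humidity-dominated winter slots with a negative elevation term
(pollution accumulates over the low plain), POI/road-dominated summer
slots — with noise SDs around 11–15 μg·m⁻³ (winter) and 4 μg·m⁻³
(summer). The met covariates in the truth are defined as the
*kriged-to-station* values, the same quantity the pipeline uses as a
predictor, which makes the noiseless identity exact: with σ = 0 the full
pipeline returns R² = 1 and zero CV error.

What the generator does *not* emulate: chemistry and transport,
regional advection, traffic dynamics, anisotropy or non-stationarity of
the meteorological fields, measurement error structure, and the
geography of any real city. Passing tests on synthetic data therefore
demonstrate the correctness and self-consistency of the machinery, not
predictive validity on real monitoring networks.

## Problem sizes and numerical tolerances

The test suite runs the full 12-slot study at the default 35-station
city; geometry oracles compare against 100k-point stratified
Monte-Carlo sampling on 20 seeded scenes (tolerance 1%); the
parameter-recovery study uses 50 seeded cities with 200 stations each, a
three-variable truth (relative humidity, catering within 900 m,
elevation) and noise at 10% of the signal SD. Exact-fit identities are
asserted at 1e-6–1e-9; kriging weight sums at 1e-10.

## Known limitations

* **Stepwise overselection.** With ~27 post-screening candidates and an
  entry threshold of p < 0.05, forward selection's family-wise
  false-entry probability per fit is large (roughly
  $1 - 0.95^{m}$ across $m$ effectively independent candidates), so the
  selected support typically contains the true variables *plus* one or
  more spurious terms, and occasionally a neighbouring buffer radius is
  screened in place of the true one (adjacent-radius correlations are
  ~0.95, and the marginal Spearman criterion is contaminated by the
  other terms of the response). This is a property of the published
  procedure itself, not of its implementation — the engine recovers
  noiseless supports exactly — and the recovery study quantifies it;
  its support-recovery rates fall well short of what one might hope
  for. Shrinkage selectors would behave better but are out of scope:
  the method implemented is the method described.
* **Small n.** Hourly models at ~35 stations are weakly identified;
  different seeds select different small models of similar fit, exactly
  as different published slots retain different predictors.
* **Linearity.** The model is linear by construction; threshold or
  saturation behaviour of, e.g., humidity is not representable.
* **Planar geometry only.** All layers must share one projected metric
  CRS; the package performs no geodesy and no reprojection.
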