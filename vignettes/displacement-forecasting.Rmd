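---
title: "Forecasting tropical-cyclone displacement: models, calibration and sensitivity"
author: "cycloneImpact"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Forecasting tropical-cyclone displacement: models, calibration and sensitivity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cycloneImpact)
```

# The forecasting problem

When a tropical cyclone (TC) approaches inhabited coastlines, humanitarian
agencies need more than a wind forecast: they need an estimate of *how many
people, and where,* are at risk of being displaced. `cycloneImpact`
implements an impact-based forecast that chains three components:

1. **Hazard** — an ensemble of TC track forecasts, each converted to a
   gridded field of lifetime-maximum 1-minute sustained wind at 10 m via a
   parametric pressure–wind model;
2. **Exposure** — a gridded population-count layer evaluated at the same
   cell centres;
3. **Vulnerability** — a calibrated sigmoid *impact function* mapping wind
   speed to the fraction of exposed people displaced.

The displacement at cell $j$ under member $m$ is $I_j = E_j\,f(V_{j,m})$,
and the forecast quantity is the total $D_m = \sum_j I_j$ across the
ensemble. Because each component is uncertain, the package wraps the chain
in a global quasi-Monte-Carlo uncertainty analysis and reports first-order
Sobol sensitivity indices per uncertain input, overall, per grid cell, and
as a function of forecast lead time.

# Hazard: the parametric wind model

Track files carry 6-hourly fixes (position, central pressure $p_{cen}$,
environmental pressure $p_{env}$, optionally reported maximum wind and
radius of maximum wind), which `interpolateTrack()` refines to 1-hourly
fixes by piecewise-linear interpolation in every channel — the least
structured choice consistent with hourly evaluation, and idempotent at the
native step.

At each hourly fix the surface Holland shape parameter is the regression

$$b_s = -4.4\times 10^{-5}\,\Delta p^2 + 0.01\,\Delta p
  + 0.03\,\tfrac{\partial \Delta p}{\partial t} - 0.014\,|\varphi|
  + 0.15\,v_t^{x} + 1.0,\qquad x = 0.6\left(1 - \tfrac{\Delta p}{215}\right),$$

with $\Delta p = p_{env} - p_{cen}$ in hPa, latitude $\varphi$ in degrees
and translation speed $v_t$ in m/s, clamped to $[1.0, 2.5]$. The peak wind
follows from $v_{max} = \sqrt{100\,b_s\,\Delta p / (\rho e)}$ with constant
surface air density $\rho = 1.15\ \mathrm{kg\,m^{-3}}$; the Coriolis term of
gradient-balance formulations is omitted (cyclostrophic surface
simplification). Outside the radius of maximum wind $r_{max}$ the radial
profile is

$$v(r) = v_{max}\left[\left(\tfrac{r_{max}}{r}\right)^{b_s}
  \exp\!\left(1-\left(\tfrac{r_{max}}{r}\right)^{b_s}\right)\right]^{0.5},$$

inside it a linear ramp from zero at the centre (the inner core is not
resolved by this class of model, and exposed cells essentially never sit
inside $r_{max}$ at 150-arcsec resolution); the wind is exactly zero beyond
a 300 km cutoff. Distances are haversine on a 6371 km sphere.

Choices a user can override through `windModelParams()`:

* **Translational asymmetry** (`asym_on`, default on): moving storms are
  stronger right of track (Northern Hemisphere sense). We add
  $v_t\,r\,r_{max}/(r^2+r_{max}^2)\cos(\theta-\theta_{track})$, capped so
  the total never exceeds $v_{max}+v_t$. Parametric asymmetry corrections
  differ across the literature; this attenuated-cosine form decays both at
  the centre and far field and is switchable because no single form is
  canonical.
* **$r_{max}$ fallback** (`r_max_tiered`): forecast files rarely report
  $r_{max}$. We default to a pressure-tiered table (deficit < 25 hPa →
  50 km, 25–50 → 40 km, > 50 → 30 km), reflecting that intense storms have
  compact eyewalls; a constant `r_max_default = 40` km is available. This is
  a pragmatic stand-in, flagged here because modelled peak winds at a cell
  are sensitive to it.
* **Wind-averaging convention** (`wind_factor`, default 1.0): hazard
  intensity is defined as 1-minute sustained wind. Agencies reporting
  10-minute means can be converted with `wind_factor = 1/0.88`. We default
  to "no conversion" and document it rather than silently rescaling.
* **Intensity precedence**: a reported maximum wind, when present, is used
  as the profile peak (respecting agency best estimates); otherwise the
  peak comes from the pressure deficit.

The hazard is evaluated directly at exposure cell centres (150 arcsec on
land, about 4 km), avoiding any population resampling; a coarser ocean grid
is only ever a map-output concern, since impacts live on land cells.

# Exposure

`readPopulation()` reads ESRI ASCII grids of person counts (cell-centre
registration, half-open cell extents, nodata mapped to 0 so every cell
participates in sums). The only exposure uncertainty modelled is a
homogeneous scaling of the total, uniform on $[0.8, 1.2]$: population
products ship no cell-level uncertainty, so a total-count proxy is the
honest option. Locational uncertainty (where the clusters actually are) is
deliberately *not* modelled, and the sensitivity results must be read
accordingly: a small exposure index means the forecast is insensitive to
homogeneous rescaling, not that exposure data quality is unimportant.

# Vulnerability: sigmoid impact functions and calibration

The impact function is a third-order sigmoid
$f(V) = s\,x^3/(1+x^3)$, $x = \max(V - V_{thresh}, 0)/(V_{half}-V_{thresh})$,
zero below $V_{thresh}$, half its asymptote $s$ at $V_{half}$.

**Free parameters.** We calibrate $V_{half}$ only, fixing
$V_{thresh} = 25.7$ m/s (the tropical-storm wind threshold widely used in
regional wind-damage calibration) and $s = 1$. With country-level event
totals as the only observable, a single well-identified parameter per
region is all the data can support; both fixed values are constructor
arguments and can be freed by supplying different constants.

**Regional fit.** `calibrateRegion()` minimises the root-mean-square
fraction error
$\mathrm{RMSF} = \exp\!\sqrt{\tfrac1N\sum_i \ln^2(m_i/o_i)}$
over a region's events ($m_i$ modeled, $o_i$ reported totals, both floored
at one person so zero-impact events stay finite). RMSF is multiplicative —
1 is perfect, 2 means a typical factor-2 error in either direction — which
suits observations spanning persons to millions. The optimiser is a
deterministic bounded scalar search on $V_{half} \in [25.8, 150]$ m/s with
0.01 m/s tolerance; calibration is therefore seed-free.

**Per-event fits and the function bundle.** For uncertainty analysis we do
not sample the regional optimum's confidence interval; instead each event
gets its own $V_{half}$ (the modeled total is strictly decreasing in
$V_{half}$, so a bracketed root search finds the exact match, clamping at
the bounds when the reported total is unattainable; zero-impact events
return an unusable sentinel). The *bundle* retains the per-event functions
inside the central 80% of the empirical $V_{half}$ distribution —
rank-based quantiles with ties broken by event id, for bit-reproducibility.
This discrete family deliberately spans more vulnerability variation than
the regional optimiser's own error bar: for single-event forecasting the
spread across plausible events is the better description of what might
happen.

# Uncertainty and sensitivity

Three uncertain inputs are sampled jointly: ensemble member (uniform over
the 51 members), exposure scale (uniform on $[0.8, 1.2]$) and impact
function (uniform over the bundle). `buildDesign()` draws scrambled Sobol
points (Joe–Kuo direction numbers; seeded random digital shift) in six
dimensions, splits them into base matrices $A$ and $B$ and cross matrices
$AB_i$, so `base_n` $\times\,(D+2)$ model runs yield all first-order
indices. The default `base_n = 2048` gives 10,240 runs. Categorical inputs
enter through floor-mapping of the unit interval ordered by id; the index
then measures variance explained by the categorical choice under that
(arbitrary but fixed) ordering — a caveat inherent to putting unordered
inputs in a variance decomposition.

Because the total impact is exactly linear in the exposure scale,
`runSamples()` computes the per-(member, function) totals once and applies
the scale multiplicatively; a test verifies this caching is
output-identical to naive re-evaluation.

`sobolFirstOrder()` uses the estimator
$S_i = \overline{f_B\,(f_{AB_i}-f_A)}/\widehat{\mathrm{Var}}(Y)$ with the
variance taken over the pooled $A$ and $B$ outputs. Confidence intervals
are percentile bootstrap over design rows (1000 resamples by default),
resampling the same rows in $f_A$, $f_B$ and every $f_{AB_i}$ so the cross
structure survives. Zero-variance outputs define all indices as 0; negative
point estimates (possible for near-inert inputs) are reported as-is, and
clipped to zero only in the per-cell dominant-input map. Per-cell indices
are computed in a second streaming pass over blocks of cells to bound
memory; cells with output variance below $10^{-12}$ persons$^2$ are flagged
"none".

`leadTimeSweep()` repeats the analysis for ensembles issued at successive
initialisation times; lead time is the interval to the parent track's
landfall on a land mask (reported in days to one decimal; if the parent
never lands, the last fix is used with a warning). `aggregateSweeps()`
reduces many events to boxplot statistics per input and lead time.

# The synthetic study system

All tests and the acceptance run use seeded generators instead of external
downloads. They emulate, at full pipeline scale:

* **Tracks** (`makeParentTrack`, `makeEnsemble`): constant-heading,
  constant-speed motion toward a circular island, pressure deficit ramping
  linearly from 10 hPa to a 60 hPa peak at landfall (a strong TC), ambient
  pressure 1010 hPa; members perturb positions by cumulative along/cross
  random walks (15 km per 6 h step) and pressure by a 2 hPa/step walk, so
  spread grows with forecast step as in operational ensembles. Member 0 is
  the unperturbed parent. `makeHitMissEnsemble` steers an exact fraction of
  members wide of the island to study bimodal forecast distributions.
* **Population** (`makePopulation`): a 200 × 200 cell grid at 150 arcsec
  centred on an 80 km-radius island holding 900,000 people in five Gaussian
  coastal clusters (15 km width), rescaled to the exact configured total,
  zero over the ocean. The numbers are of the order of the Fijian islands,
  where hit-or-miss forecast regimes are prominent.
* **Displacement catalogues** (`makeEventCatalog`): storms crossing the
  island from random directions (peak deficit uniform 30–80 hPa, speed
  3–7 m/s), with reported displacement equal to the modeled total under a
  known impact function times multiplicative lognormal noise
  ($\sigma = 0.2$ by default). Observation-error models for displacement
  records are not established; lognormal noise is the natural multiplicative
  choice and its $\sigma$ is exposed.

What the generators do *not* emulate — and hence what green tests do not
establish about real data: forecast biases and non-Gaussian ensemble
perturbation structure, real coastline and terrain effects on wind,
dasymetric population placement errors, sub-hazards (surge, rain, flood)
and compound events, reporting heterogeneity in displacement databases, and
trapped or immobile populations.

# Numerical and reproducibility choices

* One seed argument drives every stochastic step (Sobol scrambling,
  bootstrap, synthetic noise); generators save and restore the caller's RNG
  state. Calibration and wind-field evaluation are deterministic.
* Longitudes are stored unwrapped along each track and grid (the island
  case straddles the antimeridian) and normalised to $[-180, 180)$ only at
  I/O boundaries and inside geodesic calls.
* Problem sizes used by the shipped tests and acceptance run: 51-member
  ensembles on 200 × 200 grids with `base_n = 2048` (10,240 runs, 1000
  bootstrap resamples) for the headline pipeline; smaller grids (24–80
  cells a side) and designs (`base_n` 64–1024) for unit-level properties.
  These sizes were chosen as the smallest that exercise the full study
  conditions faithfully.
* Degenerate inputs: empty grids, single-fix tracks, zero-reported events,
  constant outputs and single-function bundles all have defined behaviour
  (errors, sentinels, or all-zero indices) covered by tests.

# Known limitations

The wind model is a parametric idealisation: no boundary-layer physics,
terrain roughness or gust structure, and the inner-core ramp is schematic.
Displacement is modelled as a direct function of wind alone; calibrated
functions implicitly absorb surge, rain, evacuation practice and reporting
culture, which is why they are regional and why the bundle spread is wide.
The exposure uncertainty is a total-count proxy only. Sobol indices for
categorical inputs depend on the id ordering, and first-order indices do
not capture interactions (no total-order indices are computed).
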