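---
title: "Full-season green LAI estimation: models, parameters and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Full-season green LAI estimation: models, parameters and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(laiseason)
```

## The estimation problem

Green leaf area index (LAI, one-sided green leaf area per unit ground area,
m²/m²) drives light interception and hence biomass formation, so daily LAI
through the whole season is the quantity a grower or yield model actually
needs. No single observation stream delivers it. Optical retrievals from
multispectral imagery are accurate while the canopy is open, but in the
rainy mid season acquisitions are sparse, and late in the season two
physical effects corrupt them: canopy reflectance saturates (it approaches
a leaf-colored asymptote, so the indices stop responding to LAI) and brown,
senescing leaves change the spectrum while contributing no green area. A
daily crop growth model has none of these problems but accumulates
calibration error the longer it runs unconstrained.

The package therefore switches estimator by phenological stage:

1. **Early stage** (season start to 14 July): a per-date linear regression
   of field LAI on the best vegetation index, applied to each flight's
   reflectance and interpolated daily.
2. **Mid stage** (to 11 August): ensemble Kalman filter (EnKF)
   assimilation of the daily RS-based LAI into the crop model, run from the
   season start.
3. **Late stage** (from 12 August): a hybrid — the same assimilation up to
   tasseling (development stage DVS = 1), after which the model free-runs
   to maturity and the corrupted late-season retrievals are never used.

The stage boundaries are the floor midpoints of the three field-campaign
dates (29 June, 30 July, 25 August → day-of-year 195 and 224); both printed
boundary dates are inclusive.

## Vegetation-index stage

Five indices are computed from five-band reflectance (blue 490, green 550,
red 680, red edge 720, NIR 800 nm): NDVI, RVI, OSAVI, EVI2 and MTVI2. Per
campaign date the index with the largest |Pearson r| against field LAI is
selected (ties resolve in the listing order above) and an ordinary
least-squares model LAI = a·VI + b is fitted — LAI on VI, matching the use
of the fitted line as a direct estimator. Correlation significance uses the
standard two-sided t test, t = r√((n−2)/(1−r²)), classed `**` (p < 0.01),
`*` (p < 0.05) or `ns`. Negative LAI predictions are clamped to zero (a
physical bound; the clamp count is reported). Between flights, the per-date
plot-mean predictions are interpolated in time by inverse distance
weighting, w ∝ |Δt|⁻², which passes exactly through the flight-day values;
LAI is interpolated, never model coefficients, so each flight keeps the
model fitted nearest it in time.

## The crop simulator

The forecast operator is a reduced-order daily simulator that keeps the
parameter semantics of the calibrated spring-maize set while compressing
the process detail of a full crop model:

* **Phenology.** Effective temperature Teff = max(0, (Tmax+Tmin)/2 − 8 °C)
  accumulates into thermal time; DVS = tt/TSUM1 before anthesis and
  1 + (tt−TSUM1)/TSUM2 after, clamped at 2. TSUM1 = 890, TSUM2 = 710 °C·d.
  The first day with DVS ≥ 1 is exactly the first day thermal time reaches
  TSUM1 — several tests and the hybrid switch rely on this exactness.
* **Growth.** Gross daily growth G = lue · radiation ·
  (1 − exp(−k·LAI)) · f_water · f_nutrient, with extinction k = 0.6 and
  light-use efficiency lue = 22 kg ha⁻¹ per MJ m⁻² d⁻¹ — a gross value
  before the conversion losses below, consistent with maize radiation-use
  efficiencies once conversion is applied. The interception term floors LAI
  at 0.01 so a canopy zeroed by an aggressive analysis update can
  re-establish (a stand-in for temperature-driven juvenile growth in full
  models).
* **Partitioning.** G splits by DVS-dependent piecewise-linear tables:
  the root share first (FRTB, 0.40 falling to 0), the remainder across
  leaves/stems/storage (FLTB/FSTB/FOTB) with conversion efficiencies
  CVL = 0.64, CVS = 0.66, CVO = 0.81, CVR = 0.70 kg/kg. The leaf fraction
  is constant (0.62) through the vegetative phase and falls after
  DVS = 1 — the flat early plateau matches maize partitioning patterns and
  keeps early-season LAI monotone in TSUM1, which the per-date calibration
  needs for a well-posed single-parameter fit. Knot values at late DVS
  (FLTB 0.12, FOTB 0.69 near DVS 1.3) follow the reported late-season
  partitioning of the calibrated crop. At every knot FLTB+FSTB+FOTB = 1.
* **Senescence.** Each day's leaf growth forms a cohort carrying its LAI
  increment (specific leaf area 0.0022 ha/kg). Cohorts age by
  Teff/(35 − 8) — SPAN = 28 is a life span in days at 35 °C — and a cohort
  older than SPAN moves its area from green to brown LAI. Brown LAI only
  perturbs synthetic reflectance; it never counts as green.
* **Water and nutrients.** A one-bucket soil of rooting depth
  RDMCR = 2.4 m: sm gains precipitation and loses a crop demand of
  4 mm/d scaled by f_water, clipped to [0, SM0]. f_water ramps linearly
  from 0 at wilting point (SMW 0.20) to 1 at field capacity (SMFCF 0.46).
  f_nutrient is a Liebig minimum of saturating responses x/(x+h) over
  available N, P, K with half-saturations h = 100/9 mg/kg, so 100 mg/kg of
  each gives ≈ 0.9 — a deliberately simple surrogate for a full
  soil-nutrient submodel, driven directly by measured soil nutrients.

Pools are floored at zero and cumulative pool increments balance cumulative
converted assimilate to 1e-9 relative (tested).

## Calibration

Parameters that field data cannot pin down are fitted to the plot-mean
field LAI: one bounded derivative-free optimization per campaign date
(squared LAI error on that date), then the arithmetic mean of the per-date
optima. One free parameter uses Brent's method with the endpoints checked
explicitly (so an unreachable observation pins the result to a bound and is
flagged); several use Nelder–Mead with clamped bounds and one restart,
≈200 evaluations per date. Bounds of ±20% around the prior value keep the
single-parameter problem single-rooted. With noise-free synthetic
observations this recovers the generating TSUM1 to well under 1%; with the
default noisy campaigns it lands within ~1–2%, the early date being the
least informative.

## EnKF assimilation

The state is green LAI with an identity observation operator — the
minimal choice consistent with LAI observations. Per day, every member is
advanced by the crop model (each member carries its own full mechanistic
state including soil moisture) and perturbed with additive Gaussian process
noise of sd 5% of its LAI. On observation days a perturbed-observation
update is applied: observation ensemble Dt = y + N(0, (0.05 + 0.1·y)²),
sample covariances with divisor N−1, gain K = Ac(Ac+Dc)⁻¹, member-wise
analysis Aa = Af + K(Dt − Af), LAI floored at 0 and pushed back into the
mechanistic state by rescaling every live cohort (ages unchanged) and the
leaf biomass pool proportionally. The absolute observation-noise floor of
0.05 m²/m² prevents a reported LAI of 0 from acting as an infinitely
precise observation that would zero the whole ensemble. Ensemble size
defaults to 50; the initial ensemble is a multiplicative lognormal
perturbation (sd 10%) of the initial state. All draws flow from one seed,
so runs are bit-reproducible.

**Filter divergence** — the ensemble collapsing until observations are
ignored — is countered by the expansion parameter
E = R·N·σ₁²/(D·σ₂²), with R a uniform(0,1) draw, D the window length in
days, N the current day index, σ₁² the temporal variance of the RS-based
LAI over days 1..N and σ₂² that of the forecast-mean LAI. When
σ₁²/σ₂² > 4 (strictly) and E ≥ 1, the gain is multiplied by E; the
inflated gain is clipped at 1 so the analysis cannot overshoot past the
observation (the clip is a stability choice and is recorded in the gain
log). The guard needs at least two days of history; with σ₂² = 0 it is
skipped with a warning. On a collapsed-ensemble scalar season with
drifting truth, enabling the guard strictly reduces the final-day error at
every tested seed.

## Hybrid stage and the combined season

Phenology is weather-driven and identical across members, so the DVS = 1
switch day is known in advance; the hybrid assimilates up to that day,
collapses the ensemble to its mean state (cohort structure is shared —
updates only rescale cohort areas — so the mean state is exact), and
free-runs deterministically to season end. After the switch the trajectory
satisfies the daily recursion bit-exactly from the switch state, and with
no observations at all the hybrid *is* the free-running simulator. The
combined season estimate is assembled per calendar day from the three
methods with the stage labels recorded; the full pipeline operates on the
plot-mean trajectory (per-quadrat maps remain available from the VI stage),
which matches how the calibration target and seasonal trajectories are
defined and keeps ensemble runs cheap.

## Evaluation statistics

R² is the fitted-line form Σ(L_f − L̄_obs)²/Σ(L_obs − L̄_obs)² with
L_f = a·L + b fitted by least squares (estimates independent, observations
dependent); for that fit it equals the squared Pearson correlation (tested
to 1e-10). RMSE is computed on the *raw* estimates, √(Σ(L − L_obs)²/n) —
so the pair is deliberately not the usual R²/RMSE couple: a constant
offset keeps R² = 1 but pays fully in RMSE. CV = SD/mean·100% uses the
sample SD (n−1), consistent with the covariance convention.

## What the synthetic scene emulates — and what it does not

The generator reproduces the study conditions end to end: a ~160-day
temperate season (sinusoidal mean temperature, seasonal radiation,
intermittent rain), 30 quadrats with soil nutrients drawn in the observed
spans (N 40–410, P 10–80, K 20–340 mg/kg), per-quadrat true LAI from the
simulator, three field campaigns (day-of-year 180/211/237, additive LAI
noise sd 0.2 m²/m², truncated at 0 — the order of the reported field
RMSEs) and six flight dates of five-band reflectance. Reflectance follows
Beer–Lambert soil/leaf mixing, ρ = ρ_soil + (ρ_mix − ρ_soil)(1 −
exp(−k·LAI)), with the green/brown asymptote mixture weighted by LAI
fractions — this produces exactly the two late-season failure modes:
index saturation (NDVI is strictly increasing but strictly concave in LAI)
and browning (NIR falls toward the brown asymptote, red rises). Band
asymptotes and extinctions are generator configuration, not measured
values; the brown-LAI schedule is whatever the cohort model produces after
DVS = 1 (no quantitative senescence trajectory is claimed). The scene has
no radiative-transfer physics, no atmospheric or geometric artifacts, no
spatial correlation between quadrats and no multi-year variability — so
passing tests demonstrate the estimation machinery is correct under the
stated failure modes, not that the accuracies transfer to any particular
field.

The estimation experiments bias the model (lue 18 vs the generating 22,
an ~18% deficit) so the free run accumulates error the way an imperfectly
calibrated model does; on those conditions the combined estimate's
full-season RMSE beats each single method at every tested seed.

## Problem sizes and runtime choices

Default experiments use one 160-day season, 30 quadrats, 50 ensemble
members (1000 for the linear-Gaussian oracle check, where the analysis
means match the exact Kalman filter within 5% over 30 steps), 10 seeds for
the paired method comparisons, and Brent budgets of ~50 evaluations per
calibration date. These sizes make every experiment reproducible on a
single CPU in minutes while leaving the Monte-Carlo tolerances
comfortable.

## Known limitations

* The crop surrogate has no CO₂ response, photoperiod, pests, or
  potential/water-limited production-level switch; stress is purely
  multiplicative.
* The nutrient factor is a static saturating response to the pre-season
  soil test; no in-season nutrient dynamics.
* The EnKF state is scalar (green LAI); no multivariate observation
  vectors, localization, or inflation beyond the expansion guard.
* Per-date VI models are sensor- and season-specific by construction;
  nothing here transfers across sites without refitting.
* The calendar stage boundaries assume three roughly monthly campaigns;
  with different campaign geometry the DVS-based switch is the more robust
  rule.
```{r}
sessionInfo()
```
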