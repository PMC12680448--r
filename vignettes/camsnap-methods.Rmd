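---
title: "Methods: snapshot-moment camera-trap distance sampling in camsnap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: snapshot-moment camera-trap distance sampling in camsnap}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(camsnap)
```

camsnap estimates the density of unmarked mammals from camera-trap
surveys. This vignette documents the models it fits, the assumptions they
carry, the tunable parameters, and the numerical and design choices made
where the methodology leaves the analyst a genuine decision.

## Events and relative abundance

Raw camera records are photographs; the analysis unit for abundance
indices is the *independent event*. `extract_events()` applies the
conventional sliding-gap filter: within a (station, species) series, a
photograph joins the current event if its gap to the **previous
photograph** is at most the independence window (30 min by default, the
value used throughout the camera-trap literature), and a strictly larger
gap opens a new event. Two boundary conventions matter and are fixed
here: the gap is measured photo-to-photo (not from the event's first
photo), and a gap exactly equal to the window joins the event. A window
of zero returns one event per photograph; event counts are monotone
non-increasing in the window. Both properties are tested.

`compute_rai()` reports events per 100 trap-nights. Trap-nights are kept
real-valued (a camera active 67.125 days contributes 67.125 nights). Two
aggregations are provided because they answer different questions:

* `pooled` — the exact ratio 100 · Σ events / Σ nights for a site;
* `per_camera_mean` (default) — the mean of per-station rates, with
  SE = sd/√K over K stations, stations with zero events entering as
  zeros. Only this aggregation can attach a standard error to an RAI, so
  it is the default for reporting; the two coincide when effort is equal
  across stations.

## Distance calibration

Cameras cannot measure range directly. The field protocol photographs a
150-cm pole at measured distances in front of each camera; under the
pinhole projection, image height scales as 1/distance, so distance is
linear in the ratio (actual height / image height).
`fit_calibration()` regresses *distance on the ratio* by OLS. The ratio
could equally be treated as the response; the two regressions differ
under noise, and camsnap regresses distance on ratio because predicting
distance is what the pipeline needs — the predictor (image height) is the
better-measured quantity, and the round-trip and unbiasedness properties
of this orientation are verified against the pinhole generator in the
test suite. Intercepts are estimated, not forced through zero: a free
intercept absorbs mount-height and lens offsets, and on noiseless pinhole
data OLS recovers a zero intercept exactly anyway.

Calibration is per-station (camera model and mount height vary), with a
pooled all-station model as the fallback for stations lacking their own
shots. Animal distances use an assumed shoulder height per species,
supplied as an editable lookup (cm); predictions below zero are floored
at zero and flagged rather than silently dropped. At least 3 shots
spanning at least 2 distances are required; anything less is a degenerate
design and an error.

## Detection functions

`fit_detection()` maximizes the binned (multinomial) point-transect
likelihood: for cutpoints c₀ = 0 < … < c_J = w, bin probabilities are
π_j ∝ ∫ r g(r) dr over the bin, normalized over (0, w]. Keys are uniform,
half-normal exp(−r²/2σ²), and hazard-rate 1 − exp(−(r/σ)^−b) (b > 1);
adjustment series (cosine, simple polynomial, Hermite polynomial)
multiply the key, and the product is rescaled so g(0) = 1. Defaults: w =
10 m and ten 1-m bins. The 10-m figure is the truncation radius — with
effective detection radii of 4–6 m for forest ungulates, a 10-m *bin
width* would leave a single bin and no likelihood — and the bin edges are
a configuration item.

Numerical choices:

* **Optimization** — five deterministic starts on a scale grid keyed to
  the distance quantiles; Nelder-Mead for multi-parameter fits. For
  one-parameter fits the profile is scanned on a 65-point grid and
  refined by golden-section search: the infeasible region (negative bin
  probabilities under an adjustment) is a flat penalty plateau that
  derivative-based and bracketing optimizers stall on, and the scan makes
  the 1-d case robust to it.
* **Monotonicity** — when adjustments are present, a penalty on a
  100-point grid keeps g non-increasing (and hence in [0, 1]); values
  are never silently clamped. A penalty was preferred over constrained
  optimization for robustness.
* **Selection statistics** — AIC = −2ℓ + 2k; χ² goodness of fit with
  df = J − 1 − k; ĉ = χ²/df; and the quasi-AIC convention
  QAIC = AIC + 2 when ĉ ≤ 1 (ĉ treated as 1, one parameter charged for
  estimating it) and QAIC = −2ℓ/ĉ + 2(k+1) otherwise. The +2 offset at
  ĉ ≤ 1 matches the behaviour of the standard distance-sampling software
  this convention is taken from.
* **Model choice** — `select_model()` takes the minimum-AIC fit among
  those with ĉ ≤ 1; fits with ĉ below 0.8 are admitted but flagged as
  underdispersed (underdispersion does not invalidate a fit), and if no
  fit is in the window the global AIC minimum is returned with
  `qualified = FALSE`. AIC ties (< 1e-6) break toward fewer parameters.

Every fit satisfies EDR = w√P̂ exactly, with P̂ = ∫ (2r/w²) g(r) dr by
adaptive quadrature; for the half-normal key the quadrature is verified
against the closed form (2σ²/w²)(1 − e^{−w²/2σ²}) to 1e-8.

## Density

`estimate_density()` assembles D̂ = Σn_k / (πw² Σe_k P̂) · 1/A, converts
from m⁻² to km⁻² (×10⁶), and combines three variance sources by the
delta method: CV(D)² = CV(rate)² + CV(P̂)² + CV(A)². The encounter-rate
component uses the standard effort-weighted between-station estimator;
with fewer than 10 stations a seeded station bootstrap (999 resamples)
replaces it, since the design-based estimator is unstable at small K.
CV(P̂) comes from the inverse observed information of the detection fit
via a numerical delta method.

The observation count n_k must be animal-*snapshots*: bursts and video
frames are collapsed to one observation per t-second tick
(`thin_to_snapshots()`, applied by default in the pipeline) because the
effort term e_k counts snapshots — mixing frame-level counts with
snapshot-level effort would inflate density by the burst size.

Availability A is the proportion of time animals are active. By default
it is the activity-level statistic computed from the species' own record
times: fitted circular density's mean (1/2π) divided by its maximum,
i.e. 1 for a flat curve and 0.5 for activity confined to half the day.
This assumes all animals are active at the curve's peak. A user-supplied
constant overrides it (and is the right choice when an independent
estimate exists); reports always carry the availability used. The
estimator scales exactly as 1/A, so the choice is transparent.

`stratified_density()` estimates each site/session stratum with the
pooled (global) detection function by default — strata rarely hold enough
distances to support their own curve — and combines strata into a global
estimate as the effort-weighted mean of stratum densities.

## Hurdle models and Vuong comparison

Per-station event counts on habitat covariates are modelled in two
parts: a binomial-logit hurdle for presence over all stations, and a
zero-truncated Poisson or negative-binomial count model (log link) over
occupied stations. The likelihood separates, so the hurdle part is an
ordinary logistic regression and the count part a quasi-Newton
maximization (analytic gradient for the Poisson case); SEs come from the
inverse observed information. Covariate transforms (logs) are applied
upstream in the covariate table, so coefficients are reported on the
transformed scale without automatic standardization. Degenerate data are
flagged, not hidden: constant presence (all stations occupied) leaves
the hurdle at its boundary with the count part still fitted, and
separation in the hurdle part is an error naming the offending covariate.

`vuong_test()` implements the classical non-nested statistic
z = √n · mean(m)/sd(m) on per-row log-likelihood differences, without the
AIC/BIC small-sample correction (the variant is switchable in principle;
the classical form is the default because it is the statistic as
originally defined). sd is the sample (n−1) standard deviation. Identical
per-row likelihoods are reported as "indistinguishable" rather than a
division by zero.

## Activity curves and overlap

`fit_activity()` estimates the diel activity density with a von Mises
kernel on clock time mapped linearly to the circle (no solar-time
correction). The smoothing concentration uses the standard circular
plug-in rule (the circular analogue of the normal reference bandwidth)
on the ML concentration estimate, times an `adjust` multiplier (default
1); the curve is evaluated on a fixed 512-interval grid for
reproducibility and integrates to 1 within 1e-6.

`overlap_delta()` computes Δ = ∫ min(f̂, ĝ): Δ1 as the trapezoid
integral on the grid, Δ4 as the averaged min-ratio estimator over the
two samples. The automatic rule uses Δ1 when the smaller sample has
fewer than 50 records and Δ4 otherwise, following the overlap
literature's calibration studies. `bootstrap_overlap()` attaches a
seed-deterministic bootstrap SD (resampling each species' times with
replacement). Event-level times, not every photograph, are the sampling
unit in the pipeline, to limit serial dependence within bursts.

## The synthetic generator

`simulate_ctds()` generates surveys *exactly under the estimator's
assumptions*: at every snapshot moment the number of animals in the
θ-sector within w is Poisson with mean density × sector area ×
instantaneous availability; radial positions are uniform in area (r²
uniform); detection is an independent Bernoulli g(r) per
animal-snapshot. Animals have no movement model and no between-snapshot
persistence. That is a deliberate choice: it makes recovery tests sharp
tests of the estimator's arithmetic and variance, not of robustness.
Consequently, passing recovery tests says nothing about violations real
data can show — animals dwelling in front of cameras (serially dependent
snapshots), responsive movement toward or away from cameras, measurement
error in distances, or misclassified species. The generator's defaults
are the reference study used in validation: true density 5 / km²,
half-normal σ = 4 m, w = 10 m, θ = 45°, t = 2 s, 20 stations × 20 days,
availability 0.5 as a 12-h activity window centred on noon (a schedule
whose activity-level statistic equals the availability parameter, so the
availability machinery can be validated against truth).

`simulate_calibration()` renders pole shots and animal image heights
through the same pinhole model the calibration assumes (optionally with
multiplicative Gaussian measurement noise); `simulate_hurdle_counts()`
draws presence and zero-truncated counts from supplied coefficient
vectors. All generators are deterministic given `seed`.

Validation problem sizes, chosen to make Monte-Carlo error small against
the effects under test while keeping the default suite fast: 100
replicates for the density-recovery and hurdle-recovery studies, 200
datasets of n = 500 for detection-probability bias, n = 800 rows per
hurdle replicate, 999 bootstrap replicates where a bootstrap SD is
itself under test, and 10⁵-point trapezoid oracles for overlap.

## Known limitations

* Detection-function covariates, left-truncation, and unbinned
  likelihoods as the default are not supported (an exact-distance
  likelihood is out of scope; distances are interval-recorded anyway).
* The availability statistic inherits the "all animals active at the
  peak" assumption; it is biased upward if activity is never synchronous.
* Spatially explicit densities and movement-based (REM-style) estimators
  are out of scope.
* The hurdle model treats stations as independent; spatial
  autocorrelation among stations is not modelled.
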