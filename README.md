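# camsnap

Camera-trap distance sampling with snapshot-moment effort, for estimating
the density and relative abundance of unmarked mammals — species without
individually identifiable markings, for which capture–recapture is not an
option. The package implements the full analysis chain a camera-trap
survey needs: temporal-independence filtering of photographs, relative
abundance indices, calibration-pole distance estimation, point-transect
detection functions, the snapshot-moment density estimator with an
availability correction, hurdle models of counts on habitat covariates,
and circular-kernel activity overlap — plus a ground-truth synthetic
survey generator so every stage can be validated end to end.

## The estimator

A camera at point *k* watches a sector of angle θ out to a truncation
radius *w*. Treating the camera as taking an instantaneous "snapshot"
every *t* seconds (the trigger delay, 2 s in the field protocol), its
temporal effort is the number of snapshots weighted by the fraction of the
circle it covers,

    e_k = (θ / 2π) · T_k / t ,

where *T_k* is the seconds the camera was active. With *n_k* the number of
animal–snapshot observations at point *k*, *P̂* the mean probability of
detecting an animal inside the sector (from a fitted detection function
*g(r)*), and *A* the availability (the proportion of time animals are
active, estimated from the species' own diel activity curve), density is

    D̂ = Σ n_k / (π w² Σ e_k P̂) · 1/A .

The detection function is fitted to binned radial distances by maximizing
the multinomial point-transect likelihood (bin probabilities proportional
to ∫ r g(r) dr), with uniform, half-normal, or hazard-rate keys and
cosine, simple-polynomial, or Hermite adjustment series. Model selection
follows the dispersion window ĉ ∈ [0.8, 1.0] and then minimum AIC;
QAIC, the χ² goodness of fit, the mean detection probability *P̂*, and the
effective detection radius EDR = w·√P̂ are reported for every fit.

Radial distances come from a per-station calibration: a pole of known
height (150 cm) photographed at measured distances gives an OLS line of
distance on the ratio actual height / image height, which is then applied
to each animal's image height and assumed shoulder height.

Around the density estimator sit the survey's standard companions:
RAI = 100 · events / trap-nights from 30-min independence-filtered events;
hurdle models (binomial presence + zero-truncated Poisson or negative
binomial counts, compared by AIC and Vuong's test); and von Mises kernel
activity curves with the overlap coefficient Δ and a bootstrap SD.

## Worked example

Simulate the reference synthetic study (20 stations × 20 days, true
density 5 / km², half-normal detection with σ = 4 m, availability 0.5)
and run the chain:

```r
library(camsnap)

cfg <- sim_config(seed = 42)
sim <- simulate_ctds(cfg)

events <- extract_events(sim$records, window_min = 30)
compute_rai(events, sim$deployments)
#>   site_id      species captures trap_nights    rai       se          method
#> 1  SYN_S1 barking deer      467         400 116.75 5.715572 per_camera_mean

fit <- fit_detection(sim$observations$distance_m, key = "half_normal",
                     w = 10)
fit
#> Detection fit: half_normal key, none adjustment (0 terms)
#>   n = 505 observations in 10 bins, w = 10 m
#>   loglik = -1115.707  AIC = 2233.41  QAIC = 2136.38
#>   chi2 = 8.3715 (df = 8)  c-hat = 1.0464
#>   P = 0.2999 (CV 5.25%)  EDR = 5.476 m

eff <- snapshot_effort(sim$deployments, t = 2)
counts <- data.frame(station_id = sim$deployments$station_id,
  n = as.numeric(table(factor(sim$observations$station_id,
                              sim$deployments$station_id))))
estimate_density(counts, eff, fit, availability = 0.5)[
  , c("n_total", "D", "se", "cv")]
#>   n_total        D        se     cv
#> 1     505 4.963225 0.3411374 6.8733
```

The 467 independence-filtered events over 400 trap-nights give an RAI of
116.75 events per 100 trap-nights (a deliberately dense synthetic
population). The fitted half-normal detection function estimates that an
animal inside the sector is photographed with probability 0.30, an
effective detection radius of 5.5 m of the 10 m truncation. Combining the
505 animal-snapshots with the snapshot effort, detection probability, and
the availability of 0.5 yields 4.96 ± 0.34 individuals per km² — the
generator's true density of 5 / km² sits well inside one standard error.

`run_pipeline()` executes the same chain (plus calibration, stratified
density, hurdle, and overlap stages) from a single YAML/list config and
writes CSV reports; `inst/scripts/camsnap-run.R` is a thin command-line
wrapper around it.

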