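Package: camsnap
Title: Camera-Trap Distance Sampling with Snapshot-Moment Effort
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: An analysis pipeline for camera-trap surveys of unmarked
    mammals: independence-filtered photographic events and relative
    abundance indices, calibration-pole estimation of animal-to-camera
    radial distances, binned point-transect detection functions (uniform,
    half-normal, hazard-rate keys with cosine, simple-polynomial and
    Hermite adjustments) with AIC/QAIC/c-hat selection, the
    snapshot-moment camera-trap distance-sampling density estimator with
    availability correction, hurdle count models (zero-truncated Poisson
    and negative binomial) of capture counts on habitat covariates with
    Vuong comparison, circular kernel density estimation of diel activity
    with overlap coefficients, and a synthetic-data generator with known
    ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
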