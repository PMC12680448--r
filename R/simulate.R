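#' Configuration for the synthetic camera-trap study
#'
#' Collects the ground-truth parameters of the data generator. The defaults
#' describe the reference synthetic study used throughout the package's
#' validation: 20 stations active for 20 days, a 45-degree field of view,
#' 2-second snapshot interval, 10-m truncation, half-normal detection with
#' sigma = 4 m, true density 5 individuals per km^2, and animals available
#' (active) half of the day in a single 12-h window centred on noon.
#'
#' @param seed RNG seed; every generator call is deterministic given it.
#' @param true_density Individuals per km^2.
#' @param key,detection_params Detection function (key and its natural
#'   parameters) animals are detected under.
#' @param w Truncation radius (m).
#' @param theta Field-of-view angle (radians); 45 degrees by default.
#' @param t Snapshot interval (s).
#' @param n_stations,days Stations and active days per station.
#' @param availability Proportion of the day animals are active, in (0, 1].
#' @param activity Diel schedule: `list(type = "window", center = 12)` for a
#'   block of activity of length `24 * availability` hours centred at
#'   `center`; `list(type = "uniform")` for constant availability (no diel
#'   structure); `list(type = "vonmises", mu = , kappa = , weights = )` for
#'   a smooth mixture schedule scaled to peak activity 1.
#' @param species Species label written into the tables.
#' @param calib_focal Pinhole constant: image height (px) = `calib_focal` *
#'   object height (m) / distance (m).
#' @param shoulder_height_cm Assumed shoulder height of the species (cm).
#' @param hurdle_coefs,count_coefs True coefficients (intercept first) of
#'   the hurdle presence part and zero-truncated count part.
#' @param count_family,theta_nb Count family and NB dispersion for
#'   [simulate_hurdle_counts()].
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, true_density = 5, key = "half_normal",
                       detection_params = 4, w = 10, theta = pi / 4, t = 2,
                       n_stations = 20L, days = 20,
                       availability = 0.5,
                       activity = list(type = "window", center = 12),
                       species = "barking deer", calib_focal = 200,
                       shoulder_height_cm = 65,
                       hurdle_coefs = c(-1, 1.5),
                       count_coefs = c(0.5, 0.8),
                       count_family = "ztpoisson", theta_nb = 1) {
  stopifnot(true_density >= 0, w > 0, theta > 0, theta <= 2 * pi, t > 0,
            n_stations >= 1, days > 0, availability > 0, availability <= 1,
            calib_focal > 0, shoulder_height_cm > 0)
  out <- as.list(environment())
  class(out) <- "sim_config"
  out
}

# instantaneous availability (0..1) as a function of hour of day
activity_alpha <- function(config, hours) {
  a <- config$availability
  act <- config$activity
  switch(act$type,
    uniform = rep(a, length(hours)),
    window = {
      half <- 12 * a
      center <- if (is.null(act$center)) 12 else act$center
      d <- abs(((hours - center + 12) %% 24) - 12)  # circular hour distance
      as.numeric(d < half)
    },
    vonmises = {
      x <- hours / 24 * 2 * pi
      wts <- if (is.null(act$weights)) rep(1, length(act$mu)) else
        act$weights
      wts <- wts / sum(wts)
      dens <- Reduce(`+`, Map(function(m, k, wt) wt * dvonmises(x, m, k),
                              act$mu, act$kappa, wts))
      dens / max(dens)
    },
    stop("unknown activity type '", act$type, "'"))
}

#' Simulate a snapshot-moment camera-trap survey
#'
#' Generates a survey exactly under the density estimator's assumptions: at
#' every snapshot moment of every station, the number of animals present in
#' the camera's theta-sector within the truncation radius w is Poisson with
#' mean density x sector area x instantaneous availability; positions are
#' uniform over the sector (radial distance with density 2r/w^2), and each
#' animal is detected independently with probability g(r). Detected
#' animal-snapshots become photo records time-stamped on the t-second
#' lattice. There is no movement model: snapshots are independent, which
#' makes estimator-recovery tests sharp.
#'
#' @param config A [sim_config()].
#' @return List with `deployments`, `observations` (one row per detected
#'   animal-snapshot, with its true `distance_m`), `records` (the photo
#'   table the pipeline reads), and `truth` (the config).
#' @export
simulate_ctds <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n_st <- config$n_stations
  t <- config$t
  w <- config$w
  start <- as.POSIXct("2021-02-01 00:00:00", tz = "UTC")
  station_id <- sprintf("ST%02d", seq_len(n_st))
  deployments <- data.frame(
    station_id = station_id, site_id = "SYN_S1",
    start = start, end = start + config$days * 86400,
    fov_angle_deg = config$theta * 180 / pi,
    trigger_delay_s = t, lat = NA_real_, lon = NA_real_,
    stringsAsFactors = FALSE)
  deployments$fov_angle <- config$theta

  # snapshot lattice over one day; availability weight per tick
  ticks <- seq(0, 86400 - t, by = t)
  alpha <- activity_alpha(config, ticks / 3600)
  sum_alpha_day <- sum(alpha)

  sector_area <- (config$theta / (2 * pi)) * pi * w^2
  p_bar <- mean_detection_probability(config$key, "none",
                                      config$detection_params, w)
  d_m2 <- config$true_density / 1e6
  mu_station <- d_m2 * sector_area * p_bar * sum_alpha_day * config$days

  # inverse-CDF sampler for r with pdf proportional to r g(r)
  rg <- seq(0, w, length.out = 2001L)
  pdf <- rg * detection_g(rg, config$key, "none", config$detection_params,
                          w)
  cdf <- cumsum(pdf)
  cdf <- cdf / cdf[length(cdf)]

  obs <- list()
  for (k in seq_len(n_st)) {
    n_k <- stats::rpois(1L, mu_station)
    if (n_k == 0L) next
    r <- stats::approx(cdf, rg, xout = stats::runif(n_k), ties = "ordered",
                       yleft = 0, yright = w)$y
    day <- sample.int(config$days, n_k, replace = TRUE) - 1L
    tick <- sample.int(length(ticks), n_k, replace = TRUE, prob = alpha)
    ts <- start + day * 86400 + ticks[tick]
    obs[[k]] <- data.frame(station_id = station_id[k],
                           species = config$species, timestamp = ts,
                           distance_m = r, stringsAsFactors = FALSE)
  }
  observations <- if (length(obs)) do.call(rbind, obs) else
    data.frame(station_id = character(), species = character(),
               timestamp = as.POSIXct(character(), tz = "UTC"),
               distance_m = numeric(), stringsAsFactors = FALSE)
  observations <- observations[order(observations$station_id,
                                     observations$timestamp), ]
  rownames(observations) <- NULL
  records <- observations[, c("station_id", "species", "timestamp")]
  records$count <- rep(1L, nrow(records))
  list(deployments = deployments, observations = observations,
       records = records, truth = config)
}

#' Simulate calibration-pole shots and animal image heights
#'
#' Pinhole projection: image height (px) = focal * object height (m) /
#' distance (m). Pole shots are taken at every metre (1 m to `w`) at each
#' station; animal image heights are rendered for the supplied observations
#' (typically from [simulate_ctds()]) from the species' assumed shoulder
#' height at each observation's true distance. Optional multiplicative
#' Gaussian measurement noise emulates hand-measured pixel heights.
#'
#' @param config A [sim_config()].
#' @param observations Observations data frame with `station_id`, `species`,
#'   `timestamp`, `distance_m`; `NULL` generates pole shots only.
#' @param distances Pole distances (m) per station.
#' @param noise_sd Relative (proportional) SD of image-height measurement
#'   noise; 0 gives exact pinhole heights.
#' @param pole_height_cm Calibration-pole height (150 cm field protocol).
#' @return List with `shots` and `animal_sizes` data frames.
#' @export
simulate_calibration <- function(config, observations = NULL,
                                 distances = 1:5, noise_sd = 0,
                                 pole_height_cm = 150) {
  stopifnot(inherits(config, "sim_config"), noise_sd >= 0)
  set.seed(config$seed + 1L)
  station_id <- sprintf("ST%02d", seq_len(config$n_stations))
  f <- config$calib_focal
  shots <- expand.grid(station_id = station_id,
                       true_distance_m = distances,
                       stringsAsFactors = FALSE)
  shots$pole_height_cm <- pole_height_cm
  img <- f * (pole_height_cm / 100) / shots$true_distance_m
  if (noise_sd > 0)
    img <- img * (1 + stats::rnorm(length(img), 0, noise_sd))
  shots$image_height_px <- pmax(img, 1e-6)

  animal_sizes <- NULL
  if (!is.null(observations) && nrow(observations) > 0L) {
    h_m <- config$shoulder_height_cm / 100
    img_a <- f * h_m / pmax(observations$distance_m, 1e-3)
    if (noise_sd > 0)
      img_a <- img_a * (1 + stats::rnorm(length(img_a), 0, noise_sd))
    animal_sizes <- data.frame(
      station_id = observations$station_id,
      species = observations$species,
      timestamp = observations$timestamp,
      image_height_px = pmax(img_a, 1e-6),
      assumed_shoulder_height_cm = config$shoulder_height_cm,
      stringsAsFactors = FALSE)
  }
  list(shots = shots, animal_sizes = animal_sizes)
}

# zero-truncated count samplers (inverse-CDF conditioned on Y >= 1)
rztpois <- function(n, lambda) {
  p0 <- stats::ppois(0, lambda)
  stats::qpois(p0 + stats::runif(n) * (1 - p0), lambda)
}

rztnbinom <- function(n, mu, theta) {
  p0 <- stats::pnbinom(0, size = theta, mu = mu)
  stats::qnbinom(p0 + stats::runif(n) * (1 - p0), size = theta, mu = mu)
}

#' Simulate per-station counts from a hurdle model
#'
#' Presence is Bernoulli with logit^-1(X beta); positive counts are
#' zero-truncated Poisson (or negative binomial) with log-linear mean
#' exp(X gamma). The default design is an intercept plus one standard-normal
#' covariate per coefficient beyond the intercept.
#'
#' @param config A [sim_config()] (supplies `hurdle_coefs`, `count_coefs`,
#'   `count_family`, `theta_nb`, `seed`).
#' @param n Number of stations (rows); ignored when `X` is given.
#' @param X Optional design matrix (first column the intercept), shared by
#'   both parts.
#' @return Data frame with `station_id`, covariates `x1`, `x2`, ..., and
#'   `count`; the generating values are attached as attribute `"truth"`.
#' @export
simulate_hurdle_counts <- function(config, n = 200L, X = NULL) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 2L)
  beta <- config$hurdle_coefs
  gamma <- config$count_coefs
  if (length(beta) != length(gamma))
    stop("hurdle_coefs and count_coefs must have equal length ",
         "(shared design)")
  if (is.null(X)) {
    X <- cbind(1, matrix(stats::rnorm(n * (length(beta) - 1L)), nrow = n))
  }
  n <- nrow(X)
  if (ncol(X) != length(beta)) stop("design width must match coefficients")
  pres <- stats::rbinom(n, 1L, stats::plogis(drop(X %*% beta)))
  mu <- exp(drop(X %*% gamma))
  y <- integer(n)
  pos <- pres == 1L
  if (any(pos)) {
    y[pos] <- if (config$count_family == "ztpoisson")
      rztpois(sum(pos), mu[pos]) else
      rztnbinom(sum(pos), mu[pos], config$theta_nb)
  }
  out <- data.frame(station_id = sprintf("ST%03d", seq_len(n)),
                    stringsAsFactors = FALSE)
  for (j in seq_len(ncol(X) - 1L)) out[[paste0("x", j)]] <- X[, j + 1L]
  out$count <- y
  attr(out, "truth") <- list(hurdle_coefs = beta, count_coefs = gamma,
                             count_family = config$count_family,
                             theta_nb = config$theta_nb)
  out
}
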