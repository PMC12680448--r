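#' Snapshot-moment temporal effort
#'
#' In snapshot-moment camera-trap distance sampling the survey effort at a
#' point is the number of instantaneous "snapshots" the camera makes of its
#' sector: e_k = (theta / 2 pi) * T_k / t, where theta is the field-of-view
#' angle (the fraction theta/2pi of the full circle the camera covers), T_k
#' the seconds the camera was active and t the snapshot interval in seconds
#' (the camera's trigger delay, 2 s in the field protocol).
#'
#' @param deployments Deployments data frame (`station_id`, POSIXct
#'   `start`/`end`, `fov_angle` in radians).
#' @param t Snapshot interval in seconds.
#' @return Data frame with `station_id`, `T_k` (s), `t`, `theta` (rad) and
#'   the derived effort `e_k` (snapshots).
#' @export
snapshot_effort <- function(deployments, t = 2) {
  stopifnot(t > 0)
  T_k <- trap_nights(deployments) * 86400
  if (any(T_k <= 0)) stop("deployment with non-positive active period")
  theta <- deployments$fov_angle
  data.frame(station_id = as.character(deployments$station_id),
             T_k = T_k, t = t, theta = theta,
             e_k = (theta / (2 * pi)) * T_k / t,
             stringsAsFactors = FALSE)
}

#' Snapshot-moment density estimate with variance
#'
#' The point-transect density estimator for camera-trap snapshot data:
#' D = sum(n_k) / (pi w^2 sum(e_k P_k)) * 1/A, where n_k is the number of
#' animal-snapshot observations at station k, e_k the snapshot effort, P the
#' mean detection probability within the truncation radius w, and A the
#' availability (the proportion of time animals are active and so detectable);
#' densities are reported per km^2.
#'
#' The coefficient of variation combines, by the delta method, (i) the
#' between-station encounter-rate variance of n_k/e_k (the effort-weighted
#' design-based estimator; a seeded station bootstrap replaces it when fewer
#' than `boot_below` stations are available), (ii) the CV of the fitted
#' detection probability, and (iii) the CV of the availability estimate:
#' CV(D)^2 = CV(rate)^2 + CV(P)^2 + CV(A)^2.
#'
#' @param counts Data frame with `station_id` and `n` (snapshot observations
#'   within w at that station).
#' @param efforts Effort table from [snapshot_effort()] for the same
#'   stations.
#' @param fit A `detection_fit`, or any list carrying `p_mean`, `p_cv` and
#'   `w`.
#' @param availability Proportion of time active, in (0, 1]; 1 disables the
#'   correction.
#' @param availability_cv CV (proportion, not percent) of the availability
#'   estimate; 0 when availability is a fixed constant.
#' @param boot_below Use the station bootstrap for the encounter-rate
#'   variance when the number of stations is below this value.
#' @param n_boot,boot_seed Bootstrap replicates and RNG seed.
#' @return An object of class `density_estimate` (also a one-row data
#'   frame): `scope`, `n_total`, `D` (per km^2), `se`, `cv` (percent),
#'   `availability`, `w`, `p_mean`.
#' @export
estimate_density <- function(counts, efforts, fit, availability = 1,
                             availability_cv = 0, boot_below = 10L,
                             n_boot = 999L, boot_seed = 1L) {
  stopifnot(availability > 0, availability <= 1, availability_cv >= 0)
  m <- merge(counts, efforts[, c("station_id", "e_k")], by = "station_id")
  if (nrow(m) != nrow(counts) || nrow(m) != nrow(efforts))
    stop("counts and efforts must cover the same stations")
  E <- sum(m$e_k)
  if (E <= 0) stop("total snapshot effort is zero")
  n_tot <- sum(m$n)
  w <- fit$w
  P <- fit$p_mean
  p_cv <- if (is.null(fit$p_cv) || is.na(fit$p_cv)) 0 else fit$p_cv / 100

  D_m2 <- n_tot / (pi * w^2 * E * P) / availability
  D <- D_m2 * 1e6
  if (n_tot == 0) {
    out <- density_row("station-set", n_tot, 0, NA_real_, NA_real_,
                       availability, w, P, E)
    return(out)
  }

  K <- nrow(m)
  rate <- n_tot / E
  if (K == 1L) {
    cv_rate <- NA_real_
  } else if (K < boot_below) {
    # station bootstrap of the pooled encounter rate
    rates <- local({
      old <- get0(".Random.seed", envir = globalenv())
      on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                        envir = globalenv()))
      set.seed(boot_seed)
      vapply(seq_len(n_boot), function(b) {
        i <- sample.int(K, K, replace = TRUE)
        sum(m$n[i]) / sum(m$e_k[i])
      }, numeric(1))
    })
    cv_rate <- stats::sd(rates) / rate
  } else {
    # effort-weighted between-station variance (design-based, R2-style)
    v <- K / (E^2 * (K - 1)) * sum(m$e_k^2 * (m$n / m$e_k - rate)^2)
    cv_rate <- sqrt(v) / rate
  }
  cv_D <- sqrt(sum(c(cv_rate, p_cv, availability_cv)^2, na.rm = TRUE))
  density_row("station-set", n_tot, D, D * cv_D, 100 * cv_D, availability,
              w, P, E)
}

density_row <- function(scope, n_total, D, se, cv, availability, w, p_mean,
                        effort) {
  out <- data.frame(scope = scope, n_total = n_total, D = D, se = se,
                    cv = cv, availability = availability, w = w,
                    p_mean = p_mean, effort = effort,
                    stringsAsFactors = FALSE)
  class(out) <- c("density_estimate", "data.frame")
  out
}

#' Stratified and global density
#'
#' Estimates density per stratum (site/session) and combines the strata into
#' a global estimate as the effort-weighted mean of stratum densities, with
#' weights equal to stratum snapshot effort. With
#' `mode = "pooled_detection"` the supplied global detection fit's P is used
#' in every stratum (data pooled across strata to fit one detection curve);
#' `mode = "by_stratum"` expects a `fit` element inside each stratum.
#'
#' @param strata Named list; each element a list with `counts`, `efforts`
#'   and (for `by_stratum`) `fit`, plus optional `availability` /
#'   `availability_cv`.
#' @param global_fit `detection_fit` used under `pooled_detection`.
#' @param mode `"pooled_detection"` or `"by_stratum"`.
#' @param availability,availability_cv Defaults applied to strata that do
#'   not carry their own.
#' @param ... Passed through to [estimate_density()].
#' @return A `density_estimate` data frame with one row per stratum plus a
#'   `"global"` row.
#' @export
stratified_density <- function(strata, global_fit = NULL,
                               mode = c("pooled_detection", "by_stratum"),
                               availability = 1, availability_cv = 0, ...) {
  mode <- match.arg(mode)
  if (length(strata) == 0L) stop("no strata supplied")
  if (mode == "pooled_detection" && is.null(global_fit))
    stop("pooled_detection mode needs a global_fit")
  rows <- list()
  for (nm in names(strata)) {
    s <- strata[[nm]]
    if (sum(s$efforts$e_k) <= 0) {
      warning("stratum '", nm, "' has zero effort; excluded")
      next
    }
    fit <- if (mode == "pooled_detection") global_fit else s$fit
    av <- if (!is.null(s$availability)) s$availability else availability
    av_cv <- if (!is.null(s$availability_cv)) s$availability_cv else
      availability_cv
    est <- estimate_density(s$counts, s$efforts, fit, availability = av,
                            availability_cv = av_cv, ...)
    est$scope <- nm
    rows[[nm]] <- est
  }
  if (length(rows) == 0L) stop("all strata have zero effort")
  res <- do.call(rbind, rows)
  wgt <- res$effort
  D_g <- sum(wgt * res$D) / sum(wgt)
  se_g <- sqrt(sum(wgt^2 * ifelse(is.na(res$se), 0, res$se)^2)) / sum(wgt)
  glob <- density_row("global", sum(res$n_total), D_g, se_g,
                      if (D_g > 0) 100 * se_g / D_g else NA_real_,
                      NA_real_, res$w[1], NA_real_, sum(wgt))
  out <- rbind(res, glob)
  rownames(out) <- NULL
  class(out) <- c("density_estimate", "data.frame")
  out
}

#' Availability (activity level) from a fitted diel activity curve
#'
#' The proportion of the diel cycle an animal is available for detection,
#' estimated from the species' own camera-trap record times: assuming all
#' animals are active at the curve's peak, the activity level is the mean of
#' the fitted circular density divided by its maximum, i.e.
#' 1 / (2 pi max f). A flat (uniform) curve gives 1; activity confined to
#' half the day gives 0.5. The density estimator divides by this value.
#'
#' @param curve An `activity_curve` from [fit_activity()].
#' @return Availability, a proportion in (0, 1].
#' @export
availability_from_activity <- function(curve) {
  stopifnot(inherits(curve, "activity_curve"))
  mx <- max(curve$density)
  a <- (1 / (2 * pi)) / mx
  if (!is.finite(a) || a < 1e-6)
    stop("degenerate activity curve: all mass concentrated at a point")
  min(a, 1)
}
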