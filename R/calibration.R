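#' Fit distance-calibration regressions from calibration-pole shots
#'
#' A pole of known height photographed at measured distances calibrates each
#' camera: under the pinhole projection the apparent (image) height of an
#' object scales as 1/distance, so distance is linear in the ratio
#' actual height / image height. Each station gets an ordinary least squares
#' fit of true distance on that ratio; a pooled model over all shots is also
#' fitted and serves as the fallback for stations without their own
#' calibration series (mount height and camera model vary between stations,
#' so per-station models are preferred when available).
#'
#' @param shots Data frame with columns `station_id`, `true_distance_m`,
#'   `pole_height_cm` (150 by the field protocol), `image_height_px`.
#' @param min_shots Minimum shots per station for a station-specific model
#'   (at least 3, spanning at least 2 distinct distances).
#' @return An object of class `calibration_models`: a data frame of models
#'   (`station_id`, `slope`, `intercept`, `r_squared`, `n_shots`) in which
#'   station `".pooled"` is the all-station fallback.
#' @export
fit_calibration <- function(shots, min_shots = 3L) {
  req <- c("station_id", "true_distance_m", "pole_height_cm",
           "image_height_px")
  miss <- setdiff(req, names(shots))
  if (length(miss) > 0L)
    stop("calibration table lacks columns: ", paste(miss, collapse = ", "))
  if (any(shots$true_distance_m <= 0) || any(shots$pole_height_cm <= 0) ||
      any(shots$image_height_px <= 0))
    stop("calibration distances and heights must be positive")
  min_shots <- max(3L, as.integer(min_shots))

  rows <- list()
  for (st in unique(as.character(shots$station_id))) {
    s <- shots[shots$station_id == st, ]
    if (nrow(s) >= min_shots) {
      rows[[st]] <- tryCatch(calibration_ols(s, st), error = function(e) NULL)
    }
  }
  pooled <- calibration_ols(shots, ".pooled")
  out <- do.call(rbind, c(rows, list(pooled)))
  rownames(out) <- NULL
  class(out) <- c("calibration_models", "data.frame")
  out
}

# OLS of distance on the height ratio for one station's shots
calibration_ols <- function(s, station_id) {
  ratio <- s$pole_height_cm / s$image_height_px
  if (nrow(s) < 3L)
    stop("need >= 3 calibration shots, got ", nrow(s))
  if (length(unique(signif(ratio, 12))) < 2L ||
      length(unique(signif(s$true_distance_m, 12))) < 2L)
    stop("degenerate calibration design: shots must span >= 2 distances")
  fit <- stats::lm(s$true_distance_m ~ ratio)
  co <- stats::coef(fit)
  if (co[["ratio"]] <= 0)
    stop("calibration slope is not positive at station ", station_id,
         "; check image-height units")
  data.frame(station_id = station_id,
             slope = unname(co[["ratio"]]),
             intercept = unname(co[["(Intercept)"]]),
             r_squared = suppressWarnings(summary(fit)$r.squared),
             n_shots = nrow(s), stringsAsFactors = FALSE)
}

#' Estimate animal-to-camera radial distances from image heights
#'
#' Inverts the calibration regression for each animal photograph: distance =
#' slope * (assumed shoulder height / image height) + intercept, using the
#' station's own model when present and the pooled model otherwise. Negative
#' predictions (possible when the intercept is negative and the animal is
#' very close) are floored at zero and flagged.
#'
#' @param records Data frame with `station_id`, `species`, `image_height_px`
#'   and either an `assumed_shoulder_height_cm` column or a species lookup via
#'   `shoulder_heights`.
#' @param models `calibration_models` from [fit_calibration()].
#' @param shoulder_heights Optional named numeric vector, cm of shoulder
#'   height per (normalized) species name, used where the records table lacks
#'   `assumed_shoulder_height_cm`.
#' @return The records data frame with columns `distance_m` and `floored`
#'   (logical) appended.
#' @export
estimate_radial_distance <- function(records, models,
                                     shoulder_heights = NULL) {
  if (!inherits(models, "calibration_models"))
    stop("models must come from fit_calibration()")
  if (any(records$image_height_px <= 0))
    stop("image_height_px must be positive")
  h <- records$assumed_shoulder_height_cm
  if (is.null(h)) {
    if (is.null(shoulder_heights))
      stop("no assumed_shoulder_height_cm column and no shoulder_heights table")
    sp <- normalize_species(records$species)
    h <- unname(shoulder_heights[sp])
    if (anyNA(h))
      stop("no shoulder height for species: ",
           paste(unique(sp[is.na(h)]), collapse = ", "))
  }
  if (any(h <= 0)) stop("shoulder heights must be positive")

  idx <- match(as.character(records$station_id), models$station_id)
  pooled <- match(".pooled", models$station_id)
  if (is.na(pooled) && anyNA(idx))
    stop("no calibration model (and no pooled fallback) for station(s): ",
         paste(unique(records$station_id[is.na(idx)]), collapse = ", "))
  idx[is.na(idx)] <- pooled
  d <- models$slope[idx] * (h / records$image_height_px) +
    models$intercept[idx]
  floored <- d < 0
  d[floored] <- 0
  records$distance_m <- d
  records$floored <- floored
  records
}
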