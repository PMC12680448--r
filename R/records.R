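#' Read and validate camera-trap record and deployment tables
#'
#' Reads the two delimited tables a camera-trap survey produces -- one row per
#' photograph and one row per camera deployment -- validates them against each
#' other, and returns clean data frames ready for event extraction.
#'
#' Photographs whose timestamp falls outside their deployment's active window
#' are excluded and listed in the validation report rather than silently
#' dropped. A record referring to a station absent from the deployment table is
#' a hard error: it indicates a broken join key, not a bad row.
#'
#' @param records_path Path to the records CSV with columns `station_id`,
#'   `species`, `timestamp` (ISO-8601), and optionally `count` (individuals in
#'   frame, default 1).
#' @param deployments_path Path to the deployments CSV with columns
#'   `station_id`, `site_id`, `start`, `end`, `fov_angle_deg`,
#'   `trigger_delay_s`, and optionally `lat`, `lon`.
#' @param sep Field separator, `","` by default.
#' @return A list with elements `deployments` (data frame; `fov_angle` is in
#'   radians), `records` (validated photo records with POSIXct timestamps), and
#'   `validation` (data frame of rejected rows with a `reason` column; zero
#'   rows when everything passed).
#' @export
read_records <- function(records_path, deployments_path, sep = ",") {
  dep <- utils::read.table(deployments_path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE)
  req_dep <- c("station_id", "site_id", "start", "end", "fov_angle_deg",
               "trigger_delay_s")
  miss <- setdiff(req_dep, names(dep))
  if (length(miss) > 0L)
    stop("deployments table lacks columns: ", paste(miss, collapse = ", "))
  dep$station_id <- as.character(dep$station_id)
  dep$start <- parse_timestamp(dep$start)
  dep$end <- parse_timestamp(dep$end)
  if (anyNA(dep$start) || anyNA(dep$end))
    stop("unparseable start/end timestamp in deployments table")
  if (any(dep$end <= dep$start))
    stop("deployment with end <= start: ",
         paste(dep$station_id[dep$end <= dep$start], collapse = ", "))
  dep$fov_angle <- dep$fov_angle_deg * pi / 180
  if (any(dep$fov_angle <= 0 | dep$fov_angle > 2 * pi))
    stop("fov_angle_deg must lie in (0, 360]")
  if (any(dep$trigger_delay_s <= 0))
    stop("trigger_delay_s must be positive")

  rec <- utils::read.table(records_path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE)
  req_rec <- c("station_id", "species", "timestamp")
  miss <- setdiff(req_rec, names(rec))
  if (length(miss) > 0L)
    stop("records table lacks columns: ", paste(miss, collapse = ", "))
  if (nrow(rec) == 0L) {
    rec <- data.frame(station_id = character(), species = character(),
                      timestamp = as.POSIXct(character(), tz = "UTC"),
                      count = integer())
    return(list(deployments = dep, records = rec,
                validation = empty_validation()))
  }
  rec$station_id <- as.character(rec$station_id)
  if (is.null(rec$count)) rec$count <- 1L
  rec$count[is.na(rec$count)] <- 1L
  if (any(rec$count < 1)) stop("count must be >= 1")
  rec$species <- normalize_species(rec$species)

  unknown <- setdiff(unique(rec$station_id), dep$station_id)
  if (length(unknown) > 0L)
    stop("records refer to station(s) absent from deployments: ",
         paste(sort(unknown), collapse = ", "))

  raw_ts <- rec$timestamp
  rec$timestamp <- parse_timestamp(rec$timestamp)

  idx <- match(rec$station_id, dep$station_id)
  bad_parse <- is.na(rec$timestamp)
  in_window <- !bad_parse &
    rec$timestamp >= dep$start[idx] & rec$timestamp <= dep$end[idx]

  reason <- character(nrow(rec))
  reason[bad_parse] <- "unparseable timestamp"
  reason[!bad_parse & !in_window] <- "timestamp outside deployment window"
  rejected <- which(reason != "")
  validation <- if (length(rejected) > 0L) {
    data.frame(row = rejected, station_id = rec$station_id[rejected],
               species = rec$species[rejected],
               timestamp = as.character(raw_ts[rejected]),
               reason = reason[rejected], stringsAsFactors = FALSE)
  } else empty_validation()

  rec <- rec[reason == "", c("station_id", "species", "timestamp", "count")]
  rownames(rec) <- NULL
  list(deployments = dep, records = rec, validation = validation)
}

empty_validation <- function() {
  data.frame(row = integer(), station_id = character(), species = character(),
             timestamp = character(), reason = character(),
             stringsAsFactors = FALSE)
}

#' @noRd
normalize_species <- function(x) {
  x <- tolower(trimws(as.character(x)))
  gsub("[[:space:]]+", " ", x)
}

parse_timestamp <- function(x) {
  if (inherits(x, "POSIXct")) return(x)
  out <- as.POSIXct(as.character(x),
                    tryFormats = c("%Y-%m-%dT%H:%M:%OS", "%Y-%m-%d %H:%M:%OS",
                                   "%Y-%m-%d %H:%M", "%Y-%m-%dT%H:%M",
                                   "%Y-%m-%d"),
                    tz = "UTC", optional = TRUE)
  out
}

#' Collapse photographs into independent detection events
#'
#' Applies the conventional temporal-independence filter: within one
#' (station, species) series, a photograph joins the current event when its gap
#' to the *previous photograph* is at most `window_min` minutes (a sliding
#' gap, as in camtrapR's "gap from last record"), and a strictly larger gap
#' opens a new event. A gap exactly equal to the window therefore joins.
#'
#' @param records Data frame of validated photo records (`station_id`,
#'   `species`, `timestamp`, optionally `count`).
#' @param window_min Independence window in minutes; 30 by convention.
#'   `window_min = 0` yields one event per photograph.
#' @return Data frame with one row per event: `station_id`, `species`,
#'   `start_time`, `end_time`, `n_photos`.
#' @export
extract_events <- function(records, window_min = 30) {
  if (is.null(records) || nrow(records) == 0L) {
    return(data.frame(station_id = character(), species = character(),
                      start_time = as.POSIXct(character(), tz = "UTC"),
                      end_time = as.POSIXct(character(), tz = "UTC"),
                      n_photos = integer(), stringsAsFactors = FALSE))
  }
  stopifnot(window_min >= 0)
  ord <- order(records$station_id, records$species, records$timestamp)
  r <- records[ord, ]
  same_grp <- c(FALSE, r$station_id[-1] == r$station_id[-nrow(r)] &
                         r$species[-1] == r$species[-nrow(r)])
  gap_min <- c(Inf, as.numeric(difftime(r$timestamp[-1],
                                        r$timestamp[-nrow(r)],
                                        units = "mins")))
  new_event <- !(same_grp & gap_min <= window_min)
  ev_id <- cumsum(new_event)
  agg <- function(f, x) as.vector(tapply(x, ev_id, f))
  out <- data.frame(
    station_id = agg(function(z) z[1], r$station_id),
    species = agg(function(z) z[1], r$species),
    start_time = as.POSIXct(agg(min, as.numeric(r$timestamp)),
                            origin = "1970-01-01", tz = "UTC"),
    end_time = as.POSIXct(agg(max, as.numeric(r$timestamp)),
                          origin = "1970-01-01", tz = "UTC"),
    n_photos = as.integer(agg(length, r$species)),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Trap-night effort of each deployment
#'
#' One trap night is one camera operating for 24 h; effort is kept real-valued
#' (fractional nights are not rounded). Site-level effort is the sum over that
#' site's deployments.
#'
#' @param deployments Deployments data frame with POSIXct `start` and `end`.
#' @return Numeric vector of nights, one per deployment row.
#' @export
trap_nights <- function(deployments) {
  tn <- as.numeric(difftime(deployments$end, deployments$start,
                            units = "days"))
  if (any(tn < 0)) stop("deployment with end before start")
  tn
}

#' Relative abundance index (events per 100 trap nights)
#'
#' RAI = 100 * captures / trap-nights, where captures are independent
#' photographic events. Two aggregations are available. `"pooled"` is the
#' plain ratio over the whole site. `"per_camera_mean"` (the default) computes
#' the per-station rate 100 * events_k / nights_k -- stations with zero events
#' enter as zeros -- and reports their mean with SE = sd / sqrt(n stations),
#' which is the aggregation that can produce the standard errors survey
#' reports attach to RAI tables.
#'
#' @param events Events data frame from [extract_events()].
#' @param deployments Deployments data frame (needs `station_id`, `site_id`,
#'   `start`, `end`).
#' @param method `"per_camera_mean"` or `"pooled"`.
#' @param species Optional character vector of species to report at every
#'   site (including sites where the species was never captured, giving
#'   RAI = 0). Defaults to the species observed at each site.
#' @return Data frame with one row per (site, species): `site_id`, `species`,
#'   `captures`, `trap_nights`, `rai`, `se`, `method`. Pooled SEs are `NA`.
#' @export
compute_rai <- function(events, deployments,
                        method = c("per_camera_mean", "pooled"),
                        species = NULL) {
  method <- match.arg(method)
  dep <- deployments
  dep$nights <- trap_nights(dep)
  site_nights <- tapply(dep$nights, dep$site_id, sum)
  if (any(site_nights <= 0))
    stop("site with zero trap nights: ",
         paste(names(site_nights)[site_nights <= 0], collapse = ", "))
  if (nrow(events) > 0L) {
    bad <- setdiff(unique(events$station_id), dep$station_id)
    if (length(bad) > 0L)
      stop("events at station(s) without a deployment: ",
           paste(bad, collapse = ", "))
    events$site_id <- dep$site_id[match(events$station_id, dep$station_id)]
  }
  out <- list()
  for (site in sort(unique(dep$site_id))) {
    dsite <- dep[dep$site_id == site, ]
    esite <- if (nrow(events) > 0L) events[events$site_id == site, ] else
      events
    sp_here <- if (is.null(species)) sort(unique(esite$species)) else
      normalize_species(species)
    if (length(sp_here) == 0L) next
    for (sp in sp_here) {
      n_ev_by_station <- vapply(dsite$station_id, function(st)
        sum(esite$species == sp & esite$station_id == st), numeric(1))
      captures <- sum(n_ev_by_station)
      N <- sum(dsite$nights)
      if (method == "pooled") {
        rai <- 100 * captures / N
        se <- NA_real_
      } else {
        rates <- 100 * n_ev_by_station / dsite$nights
        rai <- mean(rates)
        se <- if (length(rates) > 1L) stats::sd(rates) / sqrt(length(rates))
              else NA_real_
        if (captures == 0) se <- 0
      }
      out[[length(out) + 1L]] <- data.frame(
        site_id = site, species = sp, captures = captures, trap_nights = N,
        rai = rai, se = se, method = method, stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0L)
    return(data.frame(site_id = character(), species = character(),
                      captures = numeric(), trap_nights = numeric(),
                      rai = numeric(), se = numeric(), method = character(),
                      stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
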