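# shared fixture builders (all data generated in code; nothing on disk)

ts_utc <- function(x) as.POSIXct(x, tz = "UTC")

make_deployments <- function(n = 2, nights = 10, site = "SITE1",
                             start = "2021-02-01 00:00:00",
                             fov_deg = 45, t = 2) {
  s <- ts_utc(start)
  data.frame(station_id = sprintf("ST%02d", seq_len(n)), site_id = site,
             start = s, end = s + nights * 86400,
             fov_angle_deg = fov_deg, trigger_delay_s = t,
             fov_angle = fov_deg * pi / 180, stringsAsFactors = FALSE)
}

make_records <- function(station, species, times, count = 1L) {
  n <- max(length(station), length(times))
  data.frame(station_id = rep_len(station, n),
             species = rep_len(species, n),
             timestamp = rep_len(ts_utc(times), n),
             count = rep_len(count, n), stringsAsFactors = FALSE)
}

# write records + deployments CSVs into a temp dir, return the paths
write_tables <- function(records, deployments, dir = tempfile("tbl")) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rp <- file.path(dir, "records.csv")
  dp <- file.path(dir, "deployments.csv")
  r <- records
  r$timestamp <- format(r$timestamp, "%Y-%m-%d %H:%M:%S")
  d <- deployments
  d$fov_angle <- NULL
  d$start <- format(d$start, "%Y-%m-%d %H:%M:%S")
  d$end <- format(d$end, "%Y-%m-%d %H:%M:%S")
  utils::write.csv(r, rp, row.names = FALSE)
  utils::write.csv(d, dp, row.names = FALSE)
  list(records = rp, deployments = dp, dir = dir)
}

# Rayleigh(sigma) right-truncated at w: detected-distance law of a
# half-normal detection function around a point
r_halfnormal_detected <- function(n, sigma = 4, w = 10) {
  r <- sqrt(-2 * sigma^2 * log(runif(ceiling(n * 1.2 / (1 - exp(-w^2 /
    (2 * sigma^2)))))))
  r <- r[r <= w]
  while (length(r) < n) {
    extra <- sqrt(-2 * sigma^2 * log(runif(n)))
    r <- c(r, extra[extra <= w])
  }
  r[seq_len(n)]
}

trapz_grid <- function(curve)
  sum(diff(curve$grid) *
        (curve$density[-length(curve$density)] + curve$density[-1]) / 2)

# independent trapezoid integral of min(f, g) for two von Mises densities
oracle_vm_overlap <- function(mu1, k1, mu2, k2, n_pts = 1e5) {
  x <- seq(0, 2 * pi, length.out = n_pts + 1)
  m <- pmin(dvonmises(x, mu1, k1), dvonmises(x, mu2, k2))
  sum(diff(x) * (m[-1] + m[-length(m)]) / 2)
}
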