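test_that("read_records enforces referential integrity and the window rule", {
  dep <- make_deployments(2)
  rec <- make_records(
    c("ST01", "ST01", "ST02", "X99"), "Barking Deer",
    c("2021-02-02 08:00:00", "2021-02-03 08:00:00",
      "2021-02-04 08:00:00", "2021-02-05 08:00:00"))
  p <- write_tables(rec, dep)
  expect_error(read_records(p$records, p$deployments), "X99")

  rec2 <- rec[rec$station_id != "X99", ]
  rec2$timestamp[3] <- ts_utc("2021-01-15 08:00:00")  # before deployment
  p2 <- write_tables(rec2, dep)
  out <- read_records(p2$records, p2$deployments)
  expect_equal(nrow(out$records), 2L)
  expect_equal(nrow(out$validation), 1L)
  expect_match(out$validation$reason, "outside deployment window")
  expect_equal(out$validation$station_id, "ST02")
  # species names are trimmed and case-collapsed
  expect_true(all(out$records$species == "barking deer"))
  # fov angle converted to radians
  expect_equal(out$deployments$fov_angle, rep(pi / 4, 2))
})

test_that("read_records returns an empty record list for an empty table", {
  dep <- make_deployments(1)
  rec <- make_records(character(), character(), ts_utc(character()))
  p <- write_tables(rec, dep)
  out <- read_records(p$records, p$deployments)
  expect_equal(nrow(out$records), 0L)
  expect_equal(nrow(out$validation), 0L)
})

test_that("sliding-gap rule: boundary gap joins, larger gap splits", {
  rec <- make_records("ST01", "sambar",
                      c("2021-01-01 10:00:00", "2021-01-01 10:15:00",
                        "2021-01-01 10:45:00", "2021-01-01 12:00:00"))
  ev <- extract_events(rec, window_min = 30)
  expect_equal(nrow(ev), 2L)
  expect_equal(ev$n_photos, c(3L, 1L))
  expect_equal(ev$start_time, ts_utc(c("2021-01-01 10:00:00",
                                       "2021-01-01 12:00:00")))
  expect_equal(ev$end_time[1], ts_utc("2021-01-01 10:45:00"))
})

test_that("single photo gives a singleton event; species are independent", {
  rec1 <- make_records("ST01", "gaur", "2021-01-01 09:00:00")
  ev1 <- extract_events(rec1)
  expect_equal(nrow(ev1), 1L)
  expect_equal(ev1$n_photos, 1L)

  rec2 <- make_records("ST01", c("gaur", "sambar", "gaur", "sambar"),
                       c("2021-01-01 09:00:00", "2021-01-01 09:05:00",
                         "2021-01-01 09:10:00", "2021-01-01 09:15:00"))
  ev2 <- extract_events(rec2)
  expect_equal(sort(ev2$species), c("gaur", "sambar"))
  expect_equal(ev2$n_photos, c(2L, 2L))
})

test_that("window = 0 yields one event per photo; events decrease in window", {
  set.seed(11)
  for (rep in 1:5) {
    n <- 40
    rec <- make_records(sample(c("ST01", "ST02"), n, TRUE), "wild pig",
                        ts_utc("2021-01-01") + sort(runif(n, 0, 86400 * 2)))
    e0 <- extract_events(rec, 0)
    expect_equal(nrow(e0), n)
    counts <- vapply(c(5, 15, 30, 60, 240),
                     function(wm) nrow(extract_events(rec, wm)), numeric(1))
    expect_true(all(diff(counts) <= 0))
  }
})

test_that("trap nights are fractional days and sum to site effort", {
  dep <- make_deployments(1, nights = 10)
  expect_equal(trap_nights(dep), 10)
  dep2 <- make_deployments(40, nights = 67.125)
  expect_equal(sum(trap_nights(dep2)), 2685)
  dep3 <- make_deployments(1, nights = 2.25)
  expect_equal(trap_nights(dep3), 2.25)
})

test_that("per-camera-mean RAI matches the hand-computed example", {
  dep <- make_deployments(2, nights = 10)
  ev <- data.frame(
    station_id = c("ST01", "ST02", "ST02", "ST02"),
    species = "barking deer",
    start_time = ts_utc("2021-02-02") + (1:4) * 3600,
    end_time = ts_utc("2021-02-02") + (1:4) * 3600,
    n_photos = 1L, stringsAsFactors = FALSE)
  r <- compute_rai(ev, dep, "per_camera_mean")
  expect_equal(r$rai, 20)        # rates {10, 30}
  expect_equal(r$se, 10)         # sd 14.142 / sqrt(2)
  expect_equal(r$captures, 4)
  pooled <- compute_rai(ev, dep, "pooled")
  expect_equal(pooled$rai, 100 * 4 / 20)
})

test_that("pooled RAI is the exact ratio and invariant to station layout", {
  dep <- make_deployments(5, nights = 1249 / 5)
  set.seed(3)
  for (rep in 1:3) {
    st <- sample(dep$station_id, 23, TRUE)
    ev <- data.frame(station_id = st, species = "clouded leopard",
                     start_time = ts_utc("2021-02-02") + seq_along(st) * 3600,
                     end_time = ts_utc("2021-02-02") + seq_along(st) * 3600,
                     n_photos = 1L, stringsAsFactors = FALSE)
    r <- compute_rai(ev, dep, "pooled")
    expect_equal(r$rai, 100 * 23 / 1249)
    expect_equal(round(r$rai, 2), 1.84)
  }
})

test_that("per-camera mean equals pooled under equal effort", {
  dep <- make_deployments(4, nights = 12)
  ev <- data.frame(station_id = c("ST01", "ST01", "ST03", "ST04"),
                   species = "dhole",
                   start_time = ts_utc("2021-02-02") + (1:4) * 7200,
                   end_time = ts_utc("2021-02-02") + (1:4) * 7200,
                   n_photos = 1L, stringsAsFactors = FALSE)
  expect_equal(compute_rai(ev, dep, "per_camera_mean")$rai,
               compute_rai(ev, dep, "pooled")$rai)
})

test_that("species never captured reports RAI 0 with SE 0", {
  dep <- make_deployments(3, nights = 10)
  ev <- extract_events(make_records(character(), character(),
                                    ts_utc(character())))
  r <- compute_rai(ev, dep, species = "sambar")
  expect_equal(r$rai, 0)
  expect_equal(r$se, 0)
})
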