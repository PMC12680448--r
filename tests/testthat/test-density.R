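test_that("snapshot effort follows e = (theta / 2 pi) T / t", {
  dep <- make_deployments(1, nights = 10, fov_deg = 45)
  e <- snapshot_effort(dep, t = 2)
  expect_equal(e$e_k, 0.125 * 432000)  # 54 000 snapshots
  expect_equal(e$T_k, 864000)

  dep2 <- make_deployments(1, nights = 10, fov_deg = 360)
  expect_equal(snapshot_effort(dep2, t = 2)$e_k, 864000 / 2)

  dep3 <- make_deployments(1, nights = 1)
  expect_equal(snapshot_effort(dep3, t = 86400)$e_k, pi / 4 / (2 * pi))
})

test_that("the density estimator reproduces the worked arithmetic", {
  dep <- make_deployments(1, nights = 10, fov_deg = 45)
  eff <- snapshot_effort(dep, t = 2)
  fit <- list(p_mean = 0.5, p_cv = 0, w = 10)
  d <- estimate_density(data.frame(station_id = "ST01", n = 54), eff, fit)
  expect_equal(d$D, 54 / (pi * 100 * 54000 * 0.5) * 1e6, tolerance = 1e-12)
  expect_equal(round(d$D, 2), 6.37)
})

test_that("zero counts, linear scaling, and availability scaling hold", {
  dep <- make_deployments(6, nights = 10)
  eff <- snapshot_effort(dep, t = 2)
  fit <- list(p_mean = 0.4, p_cv = 5, w = 10)
  zero <- estimate_density(data.frame(station_id = dep$station_id, n = 0),
                           eff, fit)
  expect_equal(zero$D, 0)
  expect_true(is.na(zero$cv))

  cnt <- data.frame(station_id = dep$station_id, n = c(3, 0, 5, 2, 8, 1))
  d1 <- estimate_density(cnt, eff, fit)
  cnt2 <- cnt
  cnt2$n <- 2 * cnt$n
  d2 <- estimate_density(cnt2, eff, fit)
  expect_equal(d2$D, 2 * d1$D, tolerance = 1e-12)

  da <- estimate_density(cnt, eff, fit, availability = 0.25)
  expect_equal(da$D, d1$D / 0.25, tolerance = 1e-12)

  expect_error(estimate_density(cnt, transform(eff, e_k = 0), fit), "zero")
})

test_that("density is invariant to splitting a station at equal rate", {
  fit <- list(p_mean = 0.5, p_cv = 0, w = 10)
  dep <- make_deployments(12, nights = 10)
  eff <- snapshot_effort(dep, t = 2)
  cnt <- data.frame(station_id = dep$station_id, n = rep(c(4, 2), 6))
  d1 <- estimate_density(cnt, eff, fit)
  # split ST01 (10 nights, 4 obs) into two stations of 5 nights, 2 obs
  dep2 <- make_deployments(13, nights = 10)
  dep2$end[c(1, 13)] <- dep2$start[c(1, 13)] + 5 * 86400
  eff2 <- snapshot_effort(dep2, t = 2)
  cnt2 <- data.frame(station_id = dep2$station_id,
                     n = c(2, cnt$n[-1], 2))
  d2 <- estimate_density(cnt2, eff2, fit)
  expect_equal(d2$D, d1$D, tolerance = 1e-12)
})

test_that("stratified density is the effort-weighted mean of strata", {
  fit <- list(p_mean = 0.5, p_cv = 0, w = 10)
  mk_stratum <- function(n_obs, nights, n_st = 4, site = "S") {
    dep <- make_deployments(n_st, nights = nights, site = site)
    list(counts = data.frame(station_id = dep$station_id,
                             n = rep(n_obs / n_st, n_st)),
         efforts = snapshot_effort(dep, t = 2))
  }
  one <- mk_stratum(40, 10)
  res1 <- stratified_density(list(A = one), fit)
  direct <- estimate_density(one$counts, one$efforts, fit)
  expect_equal(res1$D[res1$scope == "A"], direct$D)
  expect_equal(res1$D[res1$scope == "global"], direct$D)

  # equal effort, densities in ratio 2:4 -> global 3
  sA <- mk_stratum(40, 10)
  sB <- mk_stratum(80, 10)
  res <- stratified_density(list(A = sA, B = sB), fit)
  dA <- res$D[res$scope == "A"]
  dB <- res$D[res$scope == "B"]
  expect_equal(dB, 2 * dA, tolerance = 1e-12)
  expect_equal(res$D[res$scope == "global"], (dA + dB) / 2)

  # effort weights 1:3 with densities d and 2d -> global 1.75 d
  sC <- mk_stratum(40, 10)
  sD <- mk_stratum(240, 30)
  res2 <- stratified_density(list(C = sC, D = sD), fit)
  dC <- res2$D[res2$scope == "C"]
  dD <- res2$D[res2$scope == "D"]
  expect_equal(res2$D[res2$scope == "global"], (1 * dC + 3 * dD) / 4,
               tolerance = 1e-12)

  # zero-effort stratum excluded with a warning
  sE <- mk_stratum(10, 10)
  sE$efforts$e_k <- 0
  expect_warning(res3 <- stratified_density(list(A = sA, E = sE), fit),
                 "zero effort")
  expect_false("E" %in% res3$scope)
})

test_that("availability equals mean/max of the activity density", {
  flat <- vonmises_curve(0, 0)
  expect_equal(availability_from_activity(flat), 1)

  # activity uniform on half the day: density 1/pi inside, 0 outside
  grid <- seq(0, 2 * pi, length.out = 513)
  half <- structure(list(times = NULL, kappa = Inf, grid = grid,
                         density = ifelse(grid < pi, 1 / pi, 0), n = 0L),
                    class = "activity_curve")
  expect_equal(availability_from_activity(half), 0.5)

  spike <- structure(list(times = NULL, kappa = Inf, grid = grid,
                          density = c(1e9, rep(0, 512)), n = 0L),
                     class = "activity_curve")
  expect_error(availability_from_activity(spike), "degenerate")
})

test_that("the estimator recovers density across true values", {
  # scaled-down companion to the main recovery study: D in {1, 20},
  # 10 stations x 8 days, 20 replicates each
  for (D_true in c(1, 20)) {
    est <- vapply(1:20, function(i) {
      cfg <- sim_config(seed = 7000 + i + D_true, true_density = D_true,
                        n_stations = 10L, days = 8)
      sim <- simulate_ctds(cfg)
      eff <- snapshot_effort(sim$deployments, cfg$t)
      cnt <- data.frame(station_id = sim$deployments$station_id,
                        n = vapply(sim$deployments$station_id, function(s)
                          sum(sim$observations$station_id == s),
                          numeric(1)))
      fit <- fit_detection(sim$observations$distance_m, "half_normal",
                           w = cfg$w)
      estimate_density(cnt, eff, fit, availability = 0.5)$D
    }, numeric(1))
    mc_se <- sd(est) / sqrt(length(est))
    expect_lt(abs(mean(est) - D_true), 3 * mc_se,
              label = paste("density recovery at D =", D_true))
  }
})
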