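test_that("key functions take their conventional closed forms", {
  expect_equal(detection_g(c(0, 3, 7, 10), "uniform"), rep(1, 4))
  expect_equal(detection_g(5, "half_normal", params = 5), exp(-0.5))
  expect_equal(detection_g(0, "half_normal", params = 5), 1)
  expect_equal(detection_g(0, "hazard_rate", params = c(4, 2.5)), 1)
  expect_equal(detection_g(4, "hazard_rate", params = c(4, 2.5)),
               1 - exp(-1))
  expect_error(detection_g(1, "half_normal", params = -1), "sigma")
  expect_error(detection_g(1, "hazard_rate", params = c(2, 0.5)), "b")
  expect_error(detection_g(-1, "uniform"), "non-negative")
})

test_that("adjusted detection functions are rescaled to g(0) = 1", {
  for (key in c("uniform", "half_normal", "hazard_rate")) {
    for (adj in c("cosine", "simple_poly", "hermite_poly")) {
      kp <- switch(key, uniform = numeric(), half_normal = 4,
                   hazard_rate = c(4, 2.5))
      g0 <- detection_g(0, key, adj, c(kp, 0.3), w = 10)
      expect_equal(g0, 1, tolerance = 1e-12,
                   label = paste(key, adj, "g(0)"))
    }
  }
})

test_that("half-normal mean detection probability matches its closed form", {
  w <- 10
  for (s in c(2, 3.5, 5, 8)) {
    p_quad <- mean_detection_probability("half_normal", "none", s, w)
    p_exact <- 2 * s^2 / w^2 * (1 - exp(-w^2 / (2 * s^2)))
    expect_equal(p_quad, p_exact, tolerance = 1e-9)
  }
  expect_equal(mean_detection_probability("uniform", w = 7), 1)
})

test_that("the uniform-key binned likelihood matches the closed form", {
  set.seed(41)
  d <- sqrt(runif(500)) * 10  # uniform in area
  fit <- fit_detection(d, "uniform", w = 10)
  edges <- fit$bin_edges
  pi_j <- diff(edges^2) / 100
  counts <- fit$counts
  expect_equal(fit$loglik, sum(counts * log(pi_j)), tolerance = 1e-9)
  expect_equal(fit$n_params, 0L)
  expect_equal(fit$p_mean, 1)
  expect_equal(fit$edr, 10)
})

test_that("exactly-expected counts give chi-square 0 and c-hat 0", {
  # uniform key: expected counts in 1-m bins of 100 obs are 1, 3, 5, ..., 19
  d <- unlist(lapply(1:10, function(j) rep(j - 0.5, 2 * j - 1)))
  fit <- fit_detection(d, "uniform", w = 10)
  expect_equal(fit$chi2, 0, tolerance = 1e-9)
  expect_equal(fit$c_hat, 0, tolerance = 1e-9)
  expect_equal(fit$df, 9L)
})

test_that("EDR = w sqrt(P) and AIC = -2 loglik + 2 k are exact identities", {
  set.seed(42)
  d <- r_halfnormal_detected(800, sigma = 4, w = 10)
  fits <- list(fit_detection(d, "half_normal", w = 10),
               fit_detection(d, "uniform", "cosine", n_adj = 2, w = 10),
               fit_detection(d, "hazard_rate", w = 10))
  for (f in fits) {
    expect_equal(f$edr, f$w * sqrt(f$p_mean), tolerance = 1e-12)
    expect_equal(f$aic, -2 * f$loglik + 2 * f$n_params, tolerance = 1e-10)
    expect_true(f$p_mean > 0 && f$p_mean <= 1)
  }
})

test_that("half-normal scale is recovered from simulated distances", {
  set.seed(43)
  d <- r_halfnormal_detected(2000, sigma = 4, w = 10)
  fit <- fit_detection(d, "half_normal", w = 10)
  se_sigma <- sqrt(fit$vcov[1, 1]) * fit$params[1]  # delta method, log scale
  expect_lt(abs(fit$params[1] - 4), 3 * se_sigma)
  expect_equal(fit$p_mean, 0.32, tolerance = 0.05)
})

test_that("adding adjustment terms never decreases the log-likelihood", {
  set.seed(44)
  d <- r_halfnormal_detected(600, sigma = 4, w = 10)
  ll <- vapply(0:2, function(m) {
    if (m == 0) fit_detection(d, "uniform", w = 10)$loglik
    else fit_detection(d, "uniform", "cosine", n_adj = m, w = 10)$loglik
  }, numeric(1))
  expect_true(all(diff(ll) >= -1e-6))
})

test_that("mean detection probability is estimated without bias", {
  # simulation-recovery across key families, 200 datasets of n = 500
  set.seed(45)
  specs <- list(
    list(key = "half_normal", pars = 4,
         gen = function(n) r_halfnormal_detected(n, 4, 10)),
    list(key = "hazard_rate", pars = c(4, 3),
         gen = function(n) {
           # rejection sampling from r g(r) on (0, 10]
           out <- numeric(0)
           while (length(out) < n) {
             r <- runif(3 * n, 0, 10)
             keep <- runif(3 * n) < (r / 10) *
               detection_g(r, "hazard_rate", params = c(4, 3))
             out <- c(out, r[keep])
           }
           out[seq_len(n)]
         }))
  for (sp in specs) {
    p_true <- mean_detection_probability(sp$key, "none", sp$pars, 10)
    p_hat <- vapply(1:200, function(i)
      fit_detection(sp$gen(500), sp$key, w = 10)$p_mean, numeric(1))
    mc_se <- sd(p_hat) / sqrt(length(p_hat))
    expect_lt(abs(mean(p_hat) - p_true), 2 * mc_se + 0.005,
              label = paste(sp$key, "P bias"))
  }
})

test_that("QAIC follows the overdispersion convention", {
  expect_equal(compute_qaic(100, -47, 0.9, 3), 102)
  expect_equal(compute_qaic(100, -47, 1.0, 3), 102)
  # c-hat > 1: rescaled likelihood plus one parameter for c-hat
  expect_equal(compute_qaic(100, -47, 1.5, 3), 94 / 1.5 + 8)
  expect_true(is.na(compute_qaic(100, -47, NA, 3)))
})

test_that("model selection applies the c-hat window then minimum AIC", {
  set.seed(46)
  base <- fit_detection(r_halfnormal_detected(300, 4, 10), "half_normal",
                        w = 10)
  mk <- function(c_hat, aic, n_params = 1L) {
    f <- base
    f$c_hat <- c_hat
    f$aic <- aic
    f$n_params <- n_params
    f
  }
  fits <- list(mk(0.9, 100), mk(0.95, 98), mk(1.3, 90))
  best <- select_model(fits)
  expect_equal(best$aic, 98)
  expect_true(best$qualified)

  expect_equal(select_model(list(base))$aic, base$aic)

  allout <- list(mk(1.4, 100), mk(1.9, 90))
  b2 <- select_model(allout)
  expect_equal(b2$aic, 90)
  expect_false(b2$qualified)

  # c-hat below the window is admitted but flagged as underdispersed
  b3 <- select_model(list(mk(0.5, 80), mk(0.95, 85)))
  expect_equal(b3$aic, 80)
  expect_true(b3$underdispersed)

  # AIC ties break toward fewer parameters
  b4 <- select_model(list(mk(0.9, 95, 3L), mk(0.9, 95, 1L)))
  expect_equal(b4$n_params, 1L)

  expect_error(select_model(list()), "no fits")
})

test_that("degenerate binned data is rejected", {
  expect_error(fit_detection(rep(0.5, 20), "half_normal", w = 10),
               "non-empty")
  expect_error(fit_detection(1:5, "half_normal", w = 10,
                             bin_edges = c(0, 5, 9)), "truncation")
})
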