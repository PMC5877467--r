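test_that("summary report totals, conservation and breath variation", {
  rep0 <- summarize_study(c(lighter_press_release = 193),
                          c(lighter_press_release = 356))
  expect_equal(rep0$counts["lighter_press_release", "total"], 549)

  empty <- summarize_study(numeric(), numeric())
  expect_true(all(empty$counts == 0))
  expect_true(is.na(empty$breath_variation_percent))

  # conservation across simulated per-portion splits
  set.seed(7)
  for (i in 1:10) {
    a <- round(runif(7, 0, 1000)); b <- round(runif(7, 0, 1000))
    nm <- c("lighter_press_release", "cigarettes_from_lighter",
            "cigarettes_self_report", "h2m_from_imu", "breaths_rip",
            "breaths_bioimpedance", "h2m_proximity")
    r <- summarize_study(setNames(a, nm), setNames(b, nm))
    expect_equal(r$counts$total, a + b)
  }

  r2 <- summarize_study(c(breaths_rip = 14232, breaths_bioimpedance = 13629),
                        c(breaths_rip = 99985, breaths_bioimpedance = 98546))
  # reported to two decimals under the bench truncation convention
  expect_equal(trunc(r2$breath_variation_percent * 100) / 100, 1.78)
  expect_error(summarize_study(c(bogus_row = 1), numeric()), "unknown")
})

test_that("cross-correlation: identity, negation, shift and the O(n^2) oracle", {
  tt <- seq(0, 10, by = 0.02)[-1]
  a <- sin(2 * pi * 0.8 * tt)
  expect_equal(xcorr_coefficient(a, a)$coefficient, 1.0)
  expect_equal(xcorr_coefficient(a, -a, max_lag = 0)$coefficient, -1.0)
  # a shifted copy of a sinusoid scores 1.0 at the shift lag
  sh <- 25L
  b <- c(a[-(1:sh)], a[1:sh])
  xc <- xcorr_coefficient(a, b)
  expect_equal(xc$coefficient, 1.0, tolerance = 1e-9)
  # scale invariance
  expect_equal(xcorr_coefficient(a, 3.7 * b)$coefficient,
               xc$coefficient, tolerance = 1e-12)
  expect_error(xcorr_coefficient(a, rep(1, length(a))), "zero-variance")

  set.seed(19)
  for (rep in 1:3) {
    x <- rnorm(500); y <- rnorm(500)
    got <- xcorr_coefficient(x, y, max_lag = 40)
    want <- oracle_xcorr(x, y, 40)
    expect_lt(abs(got$coefficient - want$coefficient), 1e-10)
    expect_equal(got$lag, want$lag)
  }
})

test_that("haversine distances match closed forms and range-check inputs", {
  expect_equal(haversine_m(10, 20, 10, 20), 0)
  # one degree of latitude on the sphere: pi * R / 180
  expect_equal(haversine_m(0, 0, 1, 0), pi * 6371000 / 180,
               tolerance = 1e-9)
  expect_equal(haversine_m(0, 0, 0, 90), pi * 6371000 / 2,
               tolerance = 1e-9)
  expect_error(haversine_m(91, 0, 0, 0), "range")
  expect_error(haversine_m(0, 200, 0, 0), "range")
})

test_that("displacement stats recover the simulated GPS noise level", {
  tl <- simulate_behavior(sim_config(seed = 23, duration_s = 10000,
                                     cigarettes_per_day = 0,
                                     walk_fraction = 0))
  g <- render_gps(tl, rate_hz = 1, indoor_hold = FALSE)
  ds <- displacement_stats(g, unique(tl$route[, c("lat_deg", "lon_deg")]))
  expect_lt(abs(ds$mean_m - 15.11) / 15.11, 0.05)  # n = 10,000 fixes
})

test_that("LC resonance formula, its inversion and count-to-MHz truncation", {
  expect_equal(resonant_frequency_hz(1, 1), 1 / (2 * pi))
  set.seed(3)
  for (i in 1:20) {
    L <- runif(1, 1e-6, 1e-5); C <- runif(1, 1e-11, 1e-9)
    expect_lt(abs(estimate_inductance(resonant_frequency_hz(L, C), C) - L) / L,
              1e-12)
  }
  expect_error(resonant_frequency_hz(-1, 1), "domain")
  expect_error(estimate_inductance(0, 1), "domain")

  expect_equal(count_to_mhz(96199.76), 9.61)
  expect_equal(count_to_mhz(100000), 10.00)
  expect_equal(count_to_mhz(89088.46), 8.90)
  # truncation, not rounding: 9.999 -> 9.99
  expect_equal(count_to_mhz(99990), 9.99)
})

test_that("linearity R^2 matches the residual-sum definition", {
  x <- c(0, 1, 1.5, 2, 2.5)
  expect_equal(linearity_r2(x, 3 + 2 * x), 1.0)
  set.seed(11)
  for (i in 1:10) {
    xx <- rnorm(20); yy <- 1 + 0.5 * xx + rnorm(20)
    fit <- stats::lsfit(xx, yy)
    want <- 1 - sum(fit$residuals^2) / sum((yy - mean(yy))^2)
    expect_lt(abs(linearity_r2(xx, yy) - want), 1e-12)
  }
  # y independent of x: R^2 collapses toward 0
  expect_lt(linearity_r2(1:50, rep(c(1, -1), 25)), 0.01)
  expect_error(linearity_r2(rep(1, 5), rnorm(5)), "degenerate")
})
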