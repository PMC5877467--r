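test_that("find_peaks agrees with a brute-force window oracle", {
  set.seed(41)
  for (rep in 1:5) {
    x <- as.numeric(stats::filter(rnorm(400), rep(1 / 7, 7),
                                  method = "convolution", sides = 2))
    x <- x[!is.na(x)]
    w <- sample(c(5L, 10L, 20L), 1)
    got <- find_peaks(x, min_dist = w)
    want <- oracle_window_peaks(x, w)
    # every oracle peak (strict window max) must be found
    expect_true(all(want %in% got))
    # and all found peaks honour the distance constraint
    if (length(got) > 1) expect_true(all(diff(got) >= w))
  }
  # prominence: small ripple on a big wave is rejected, the wave kept
  tt <- seq(0, 20, by = 0.01)
  x <- sin(2 * pi * 0.25 * tt) + 0.02 * sin(2 * pi * 5 * tt)
  expect_equal(length(find_peaks(x, min_dist = 10, min_prominence = 0.5)), 5L)
  # without the prominence floor the ripple maxima (visible near the slow
  # wave's crests, where its slope is shallow) are all retained
  expect_gt(length(find_peaks(x, min_dist = 10, min_prominence = 0.001)), 15L)
})

test_that("breath detection: sinusoid count, flat signal, noisy recovery", {
  tt <- seq(0.01, 60, by = 0.01)
  s15 <- sensor_stream("resp", list(v = sin(2 * pi * (15 / 60) * tt)), 100)
  expect_equal(n_events(detect_breaths(s15)), 15L)
  flat <- sensor_stream("resp", list(v = rep(1, 6000)), 100)
  expect_equal(n_events(detect_breaths(flat)), 0L)
  expect_equal(n_events(detect_breaths(
    sensor_stream("resp", list(v = numeric(0)), 100))), 0L)

  # 1-h noisy RIP render: within 2% of ground truth
  tl <- simulate_behavior(sim_config(seed = 61, duration_s = 3600,
                                     cigarettes_per_day = 10))
  rip <- condition(render_rip(tl), "rip")
  got <- n_events(detect_breaths(rip, invert = TRUE))
  expect_lt(abs(got - nrow(tl$breaths)) / nrow(tl$breaths), 0.02)
})

test_that("R-peaks and heart-rate summaries behave per contract", {
  # strictly regular RR = 0.75 s -> instantaneous HR 80 bpm everywhere
  rp <- event_log("ecg", kind = rep("detected_rpeak", 100),
                  t_start_s = seq(0, by = 0.75, length.out = 100))
  hr <- instantaneous_hr(rp)
  expect_true(all(abs(hr$hr_bpm - 80) < 1e-9))
  hs <- summarize_heart_rate(rp, c(20, 50), pre_s = 15, post_s = 15)
  expect_equal(hs$mean_bpm[hs$window == "smoking"], 80)
  expect_equal(hs$sd_bpm[hs$window == "smoking"], 0)

  # a window holding a single peak errors instead of returning silent zero
  sparse <- event_log("ecg", kind = rep("detected_rpeak", 3),
                      t_start_s = c(0.1, 30, 30.7))
  expect_error(summarize_heart_rate(sparse, c(29, 31), pre_s = 10,
                                    post_s = 10), "undefined-HR")
})

test_that("proximity events: noise-only silence, single excursion, merging", {
  tl_idle <- simulate_behavior(sim_config(seed = 71, duration_s = 600,
                                          cigarettes_per_day = 0))
  pr <- condition(render_proximity(tl_idle), "proximity")
  expect_equal(n_events(detect_proximity_events(pr)), 0L)

  x <- rep(7, 1000); x[301:500] <- 200  # one 2-s excursion at 100 Hz
  s <- sensor_stream("prox", list(v = x), 100)
  ev <- detect_proximity_events(s)
  expect_equal(n_events(ev), 1L)
  expect_lt(abs((ev$events$t_end_s - ev$events$t_start_s) - 2), 0.05)

  # runs separated by a sub-gap dip merge into one event
  x2 <- rep(7, 1000); x2[301:340] <- 200; x2[361:400] <- 200
  expect_equal(n_events(detect_proximity_events(
    sensor_stream("prox", list(v = x2), 100))), 1L)

  # threshold monotonicity: raising it never increases the event count
  tl <- simulate_behavior(sim_config(seed = 72, duration_s = 1800,
                                     cigarettes_per_day = 40))
  prc <- condition(render_proximity(tl), "proximity")
  n_by_thr <- vapply(c(20, 70, 120, 400), function(th)
    n_events(detect_proximity_events(
      prc, detection_params(proximity_threshold_mv = th))), integer(1))
  expect_true(all(diff(n_by_thr) <= 0))

  # clean render: one event per ground-truth puff
  pr_clean <- condition(render_proximity(tl, zero_noise()), "proximity")
  expect_equal(n_events(detect_proximity_events(pr_clean)), total_puffs(tl))
})

test_that("lighter consolidation matches the brute-force oracle", {
  # worked micro-cases
  sess <- event_log("phone", "self_report_cigarette", 100, 400)
  three <- event_log("lighter", rep("lighter_press", 3),
                     t_start_s = c(92, 95, 98), t_end_s = c(93, 96, 99))
  out <- consolidate_lighter(three, sess)
  expect_equal(n_events(out$cigarettes), 1L)
  expect_equal(out$n_false_events, 0L)

  lone <- event_log("lighter", "lighter_press", 1000, 1001)
  out2 <- consolidate_lighter(lone, sess)
  expect_equal(n_events(out2$cigarettes), 0L)
  expect_equal(out2$n_false_events, 1L)

  overlapping <- event_log("phone", rep("self_report_cigarette", 2),
                           t_start_s = c(0, 50), t_end_s = c(100, 150))
  expect_error(consolidate_lighter(lone, overlapping), "integrity")

  # randomized sessions and presses vs the exhaustive matching oracle
  set.seed(83)
  for (rep in 1:20) {
    k <- sample(1:5, 1)
    st <- sort(runif(k, 0, 5000)); en <- st + runif(k, 120, 400)
    if (k > 1) for (j in 2:k) st[j] <- max(st[j], en[j - 1] + 1)
    en <- pmax(en, st + 60)
    sessions <- event_log("phone", rep("self_report_cigarette", k),
                          t_start_s = st, t_end_s = en)
    np <- sample(0:12, 1)
    pt <- runif(np, -100, 5600)
    lighter <- event_log("lighter", rep("lighter_press", np),
                         t_start_s = pt, t_end_s = pt + 1)
    got <- consolidate_lighter(lighter, sessions)
    want <- oracle_consolidate(pt, st, en, 60)
    expect_equal(n_events(got$cigarettes), want$n_cigarettes)
    expect_equal(got$n_false_events, want$n_false)
    # conservation: discarded + grouped = total presses
    expect_equal(got$n_false_events + got$n_grouped_presses, np)
    expect_lte(n_events(got$cigarettes), np)
  }
})

test_that("usability screening finds injected removal segments", {
  tl <- simulate_behavior(sim_config(seed = 91, duration_s = 3600,
                                     cigarettes_per_day = 0))
  rip <- condition(render_rip(tl), "rip")
  bioz <- condition(render_bioimpedance(tl, rate_hz = 100), "bioimpedance")
  mask_full <- screen_usability(rip, bioz)
  expect_equal(usable_percent(mask_full), 100)

  # zero a 15-min shower segment on both sensors
  zero_seg <- function(s, t0, t1) {
    i <- (floor(t0 * s$rate_hz) + 1):min(n_samples(s), ceiling(t1 * s$rate_hz))
    s$samples[[1]][i] <- 0
    s
  }
  mask <- screen_usability(zero_seg(rip, 1200, 2100),
                           zero_seg(bioz, 1200, 2100))
  expect_equal(usable_percent(mask), (3600 - 900) / 3600 * 100)
  lab_min <- vapply(seq(30, 3570, by = 60), function(t)
    mask$label[findInterval(t, mask$t_start_s)], character(1))
  want <- ifelse(seq(30, 3570, by = 60) > 1200 & seq(30, 3570, by = 60) < 2100,
                 "removed", "usable")
  expect_gte(mean(lab_min == want), 0.99)

  # one sensor silent, the other alive -> ambiguous
  mask_amb <- screen_usability(zero_seg(rip, 1200, 2100), bioz)
  expect_true("ambiguous" %in% mask_amb$label)
  expect_false("removed" %in% mask_amb$label)
})

test_that("step and IMU gesture counting over intervals", {
  tl <- simulate_behavior(sim_config(seed = 95, duration_s = 1800,
                                     walk_fraction = 0.6,
                                     cigarettes_per_day = 20))
  ped <- render_pedometer(tl)
  expect_equal(count_steps(ped, c(500, 500)), 0)
  # windows fully inside the interval sum exactly
  full <- tl$steps$window_start_s >= 273 & tl$steps$window_start_s + 13.63 <= 1500
  inner0 <- min(tl$steps$window_start_s[full])
  inner1 <- max(tl$steps$window_start_s[full]) + 13.63
  expect_equal(count_steps(ped, c(inner0, inner1)),
               sum(tl$steps$count[full]))
  # prorating: half a window contributes half its count
  w5 <- tl$steps[5, ]
  expect_equal(count_steps(ped, c(w5$window_start_s,
                                  w5$window_start_s + 13.63 / 2)),
               w5$count / 2)

  imu <- condition(render_imu_hand(tl, zero_noise()), "imu")
  expect_equal(count_h2m_from_imu(imu), total_puffs(tl))
  expect_equal(count_h2m_from_imu(imu, detector = function(s) 42L), 42L)
})
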