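test_that("behavior simulation is deterministic, valid and rate-consistent", {
  cfg <- sim_config(seed = 101, duration_s = 7200, cigarettes_per_day = 24)
  tl1 <- simulate_behavior(cfg)
  tl2 <- simulate_behavior(cfg)
  expect_identical(tl1[names(tl1) != "config"], tl2[names(tl2) != "config"])

  # empty scenario
  tl0 <- simulate_behavior(sim_config(seed = 1, duration_s = 0))
  expect_equal(nrow(tl0$breaths), 0L)
  expect_length(tl0$cigarettes, 0L)
  expect_error(sim_config(duration_s = -5), "config")

  # invariants: puffs inside cigarettes, distances in reach, breaths ordered
  expect_true(all(diff(tl1$breaths$peak_time_s) > 0))
  for (cg in tl1$cigarettes) {
    expect_true(all(cg$puffs$t_s >= cg$t_light_s &
                      cg$puffs$t_s <= cg$t_end_s))
    expect_true(all(cg$puffs$tx_rx_distance_cm <= 15))
  }
  expect_true(all(hr_at(tl1, seq(0, 7200, by = 60)) > 0))

  # breathing stays inside the configured 12-20 breaths/min band (loosely:
  # per-hour averages)
  rate_per_min <- nrow(tl1$breaths) / (7200 / 60)
  expect_gt(rate_per_min, 11); expect_lt(rate_per_min, 21)
})

test_that("daily cigarette counts follow the configured Poisson rate", {
  n <- vapply(1:30, function(s)
    length(simulate_behavior(sim_config(seed = s, duration_s = 86400,
                                        cigarettes_per_day = 12,
                                        walk_fraction = 0))$cigarettes),
    integer(1))
  # overlap-thinning can drop a draw occasionally; mean stays near 12
  expect_gt(mean(n), 12 - 3 * sqrt(12 / 30))
  expect_lt(mean(n), 12 + 3 * sqrt(12 / 30))
})

test_that("RIP forward model matches its bench calibration and physics", {
  # static circumference, no breathing, no noise -> constant counts equal to
  # the calibration table within the floor-truncation limit
  for (i in seq_len(nrow(rip_bench))) {
    p <- rip_params(baseline_circumference_cm = rip_bench$circumference_cm[i],
                    breath_amplitude_cm = 0)
    tl <- simulate_behavior(sim_config(seed = 5, duration_s = 2,
                                       cigarettes_per_day = 0))
    s <- render_rip(tl, p, zero_noise())
    expect_equal(length(unique(s$samples$pulse_count)), 1L)
    expect_lt(abs(mean(s$samples$pulse_count) - rip_bench$mean_pulse_count[i]),
              0.001 * rip_bench$mean_pulse_count[i])
  }
  # monotone: counts at 120 cm below counts at 60 cm; inductance in band
  p60 <- rip_params(baseline_circumference_cm = 60, breath_amplitude_cm = 0)
  expect_true(all(p60$inductance_at(60:120) >= 2e-6 - 1e-9))
  expect_true(all(p60$inductance_at(60:120) <= 3e-6 + 1e-9))
  expect_true(all(diff(p60$inductance_at(60:120)) > 0))

  # breathing modulation lowers counts at breath peaks (chest expansion)
  tl <- simulate_behavior(sim_config(seed = 5, duration_s = 120,
                                     cigarettes_per_day = 0))
  s <- render_rip(tl, rip_params(), zero_noise())
  pk1 <- tl$breaths$peak_time_s[5]
  i_pk <- round(pk1 * 100) + 1
  expect_lt(s$samples$pulse_count[i_pk], max(s$samples$pulse_count))
})

test_that("renders are reproducible and respect range clipping", {
  tl <- simulate_behavior(sim_config(seed = 77, duration_s = 600,
                                     cigarettes_per_day = 48))
  expect_identical(render_rip(tl)$samples, render_rip(tl)$samples)
  expect_identical(render_ecg(tl, duration_s = 30)$samples,
                   render_ecg(tl, duration_s = 30)$samples)
  imu <- render_imu_hand(tl)
  expect_true(all(abs(imu$samples$ax) <= 8))
  expect_true(all(abs(imu$samples$gx) <= 2000))
  chest <- render_chest_accel(tl)
  expect_true(all(abs(chest$samples$az) <= 2))
  # idle channel means sit near the configured bias
  tl_idle <- simulate_behavior(sim_config(seed = 3, duration_s = 600,
                                          cigarettes_per_day = 0,
                                          walk_fraction = 0))
  imu_idle <- render_imu_hand(tl_idle)
  expect_lt(abs(mean(imu_idle$samples$ay) - 0.19), 0.01)
  expect_lt(abs(mean(imu_idle$samples$gy) - 10), 0.5)
})

test_that("ECG render places the expected beats and a clean 60 Hz option", {
  tl <- simulate_behavior(sim_config(seed = 4, duration_s = 60,
                                     cigarettes_per_day = 0,
                                     hr_baseline_bpm = 60))
  e <- render_ecg(tl, zero_noise(), powerline_mv = 0, wander_mv = 0)
  rp <- detect_rpeaks(condition(e, "ecg"))
  expect_true(abs(n_events(rp) - 60) <= 1)
  # no interference -> no 60-Hz spectral line
  x <- e$samples$ecg
  sp <- Mod(stats::fft(x))[round(60 * length(x) / 1000) + 1]
  e2 <- render_ecg(tl, zero_noise(), powerline_mv = 0.2, wander_mv = 0)
  sp2 <- Mod(stats::fft(e2$samples$ecg))[round(60 * length(x) / 1000) + 1]
  expect_lt(sp, sp2 / 100)
})

test_that("proximity render obeys its amplitude-distance contract", {
  expect_error(proximity_amplitude_mv(-1), "negative")
  d <- seq(0, 30, by = 0.5)
  expect_true(all(diff(proximity_amplitude_mv(d)) < 0))
  expect_gt(proximity_amplitude_mv(11), 70)   # in-reach puffs clear threshold
  expect_lt(proximity_amplitude_mv(20), 70)   # out of reach sinks to noise
  expect_lt(abs(proximity_amplitude_mv(0) - 2800), 1e-9)

  tl_idle <- simulate_behavior(sim_config(seed = 8, duration_s = 600,
                                          cigarettes_per_day = 0))
  pr <- render_proximity(tl_idle)
  expect_lt(abs(mean(pr$samples$proximity) - 7.31), 0.1)
})

test_that("bioimpedance shares breath peaks with the ground truth", {
  tl <- simulate_behavior(sim_config(seed = 12, duration_s = 180,
                                     cigarettes_per_day = 0))
  b <- condition(render_bioimpedance(tl), "bioimpedance")
  db <- detect_breaths(b)
  expect_equal(n_events(db), nrow(tl$breaths))
  expect_lt(max(abs(db$events$t_start_s - tl$breaths$peak_time_s)), 0.1)
})

test_that("GPS fixes hold indoors and pedometer windows conserve steps", {
  tl <- simulate_behavior(sim_config(seed = 14, duration_s = 1200,
                                     walk_fraction = 0,
                                     cigarettes_per_day = 0))
  g <- render_gps(tl, zero_noise())
  expect_equal(length(unique(g$samples$latitude_deg)), 1L)

  tl2 <- simulate_behavior(sim_config(seed = 15, duration_s = 3600,
                                      walk_fraction = 0.5,
                                      cigarettes_per_day = 0))
  ped <- render_pedometer(tl2)
  got <- sum(vapply(ped$attrs, function(a) a$step_count, numeric(1)))
  expect_equal(got, sum(tl2$steps$count))
  expect_equal(count_steps(ped, c(0, tl2$duration_s)), sum(tl2$steps$count))
})

test_that("clock drift injection is the exact inverse of compensation", {
  tl <- simulate_behavior(sim_config(seed = 16, duration_s = 3600,
                                     cigarettes_per_day = 24))
  lt <- render_lighter(tl)
  ck <- clock_model("lighter", t0_s = 0, f = 1 + 5 / 86400)
  drifted <- apply_clock_drift(lt, ck)
  back <- compensate_log(drifted, ck)
  expect_lt(max(abs(back$events$t_start_s - lt$events$t_start_s)), 1e-9)
  # f = 1 is the identity; 5 s/day reaches 5 s at day's end
  id <- apply_clock_drift(lt, clock_model("l", 0, 1))
  expect_identical(id$events, lt$events)
  expect_equal(with(clock_model("l", 0, 1 + 5 / 86400),
                    t0_s + f * (86400 - t0_s)) - 86400, 5)

  s <- render_rip(tl)
  s_d <- apply_clock_drift(s, ck)
  s_b <- compensate_stream(s_d, ck)
  expect_equal(s_b$rate_hz, s$rate_hz)
  expect_lt(abs(s_b$start_time_s - s$start_time_s), 1e-9)
})
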