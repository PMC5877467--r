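# Forward models: behavior_timeline -> raw device streams/logs.
# Each render draws its noise from a deterministic substream of the scenario
# seed, so a fixed seed reproduces every stream bit-for-bit.

#' Per-sensor noise specification
#'
#' (mean, sd) of additive sensor noise, per sensing element. Defaults are the
#' idle bench-test characterization of the hardware: each device was left
#' undisturbed on a flat surface for 10 min and the mean and standard
#' deviation of its output recorded.
#'
#' @param hand_accel_g,hand_gyro_dps,chest_accel_g,rip_count,bioimpedance_mv,ecg_mv,proximity_mv,gps_m
#'   length-2 numeric `c(mean, sd)` in the unit named by the argument.
#' @return An object of class `noise_spec`.
#' @export
noise_spec <- function(hand_accel_g = c(0.19, 0.00324),
                       hand_gyro_dps = c(10, 1.57),
                       chest_accel_g = c(0.04, 0.00416),
                       rip_count = c(5.23, 1.29),
                       bioimpedance_mv = c(0, 0),
                       ecg_mv = c(0.007, 0.003),
                       proximity_mv = c(7.31, 1.21),
                       gps_m = c(15.11, 2.639)) {
  spec <- list(hand_accel_g = hand_accel_g, hand_gyro_dps = hand_gyro_dps,
               chest_accel_g = chest_accel_g, rip_count = rip_count,
               bioimpedance_mv = bioimpedance_mv, ecg_mv = ecg_mv,
               proximity_mv = proximity_mv, gps_m = gps_m)
  for (nm in names(spec)) {
    v <- spec[[nm]]
    if (length(v) != 2L || !is.numeric(v) || v[2L] < 0)
      stop("noise entry '", nm, "' must be c(mean, sd) with sd >= 0")
  }
  structure(spec, class = "noise_spec")
}

#' @rdname noise_spec
#' @return `zero_noise()`: a `noise_spec` with every mean and sd set to 0,
#'   for noise-free renders.
#' @export
zero_noise <- function() {
  spec <- noise_spec()
  for (nm in names(spec)) spec[[nm]] <- c(0, 0)
  spec
}

#' Bench calibration table of the respiration belt oscillator
#'
#' Mean LC-oscillator pulse counts per 10-ms window recorded with the belt
#' held at four fixed simulated chest circumferences (breathless bench
#' measurement, three 1-min recordings per circumference).
#'
#' @format data frame with columns `circumference_cm`, `mean_pulse_count`.
#' @export
rip_bench <- data.frame(
  circumference_cm = c(60, 80, 100, 120),
  mean_pulse_count = c(102376.76, 96199.76, 92954.09, 89088.46))

#' Respiration-belt (RIP) oscillator model parameters
#'
#' The belt is the inductor of an LC oscillator with resonant frequency
#' f0 = 1/(2 pi sqrt(L C)); the microcontroller counts oscillator pulses per
#' 10-ms window (a 100-Hz count stream), and counts fall as the chest
#' expands because L grows with the enclosed loop area. The inductance-vs-
#' circumference curve is calibrated by inverting f0 at each bench
#' circumference ([rip_bench]) and interpolating monotonically (Hyman cubic)
#' between the four points, with linear extrapolation outside 60-120 cm.
#' An affine L(c) law was considered and rejected: it misses the bench
#' counts by up to 0.8%.
#'
#' @param c_eq_farads equivalent capacitance of the two 220-pF series
#'   capacitors (110 pF).
#' @param count_window_s pulse-count window (0.01 s, i.e. 100 Hz).
#' @param baseline_circumference_cm resting chest circumference (default the
#'   validation-study mean, 85.63 cm).
#' @param breath_amplitude_cm peak circumference excursion of a full-depth
#'   breath.
#' @param calibration data frame like [rip_bench].
#' @return Object of class `rip_params`; `$inductance_at(c_cm)` evaluates
#'   the calibrated L(c) in henries.
#' @export
rip_params <- function(c_eq_farads = 110e-12,
                       count_window_s = 0.01,
                       baseline_circumference_cm = 85.63,
                       breath_amplitude_cm = 2,
                       calibration = rip_bench) {
  stopifnot(c_eq_farads > 0, count_window_s > 0, breath_amplitude_cm >= 0)
  f0 <- calibration$mean_pulse_count / count_window_s
  L <- 1 / ((2 * pi * f0)^2 * c_eq_farads)
  sf <- stats::splinefun(calibration$circumference_cm, L, method = "hyman")
  cmin <- min(calibration$circumference_cm)
  cmax <- max(calibration$circumference_cm)
  ind_at <- function(c_cm) {
    # linear extrapolation beyond the calibrated range
    cc <- pmin(pmax(c_cm, cmin), cmax)
    sf(cc) + (c_cm - cc) * sf(cc, deriv = 1L)
  }
  p <- structure(
    list(c_eq_farads = c_eq_farads, count_window_s = count_window_s,
         baseline_circumference_cm = baseline_circumference_cm,
         breath_amplitude_cm = breath_amplitude_cm,
         calibration = calibration, inductance_at = ind_at),
    class = "rip_params")
  grid <- seq(cmin, cmax, length.out = 121L)
  Lg <- ind_at(grid)
  if (any(Lg < 2e-6 | Lg > 3e-6))
    stop("rip_params invariant violated: inductance outside 2-3 uH over ",
         cmin, "-", cmax, " cm")
  if (any(1 / (2 * pi * sqrt(Lg * c_eq_farads)) >= 16e6))
    stop("rip_params invariant violated: resonant frequency >= 16 MHz")
  p
}

# add raised-cosine bumps (center, half-width, amplitude) into x sampled at
# rate_hz starting at t0; returns modified x
add_bumps <- function(x, rate_hz, t0, centers, half_widths, amps) {
  n <- length(x)
  for (i in seq_along(centers)) {
    tc <- centers[i]; w <- half_widths[i]
    i0 <- max(1L, ceiling((tc - w - t0) * rate_hz) + 1L)
    i1 <- min(n, floor((tc + w - t0) * rate_hz) + 1L)
    if (i0 > i1) next
    tt <- t0 + (seq(i0, i1) - 1) / rate_hz
    x[i0:i1] <- x[i0:i1] + amps[i] * 0.5 * (1 + cos(pi * (tt - tc) / w))
  }
  x
}

# shared respiration modulation (0..1 scale): raised-cosine bump per breath,
# half-width capped at 45% of the gap to the nearest neighbouring breath
breath_modulation <- function(timeline, rate_hz, t0, n) {
  x <- numeric(n)
  b <- timeline$breaths
  if (!nrow(b)) return(x)
  gaps <- diff(b$peak_time_s)
  gl <- c(Inf, gaps); gr <- c(gaps, Inf)
  w <- pmin(2.0, 0.45 * pmin(gl, gr))
  w <- pmax(w, 0.3)
  t1 <- t0 + (n - 1) / rate_hz
  keep <- b$peak_time_s + w >= t0 & b$peak_time_s - w <= t1
  add_bumps(x, rate_hz, t0, b$peak_time_s[keep], w[keep], b$depth[keep])
}

render_n <- function(duration_s, rate_hz) as.integer(floor(duration_s * rate_hz))

#' Render the RIP pulse-count stream
#'
#' Chest circumference is the baseline plus a raised-cosine excursion per
#' breath; circumference maps to belt inductance via the calibrated L(c)
#' curve, inductance to oscillator frequency via f0 = 1/(2 pi sqrt(LC)), and
#' each 10-ms window records `floor(f0 * window)` pulses plus rounded
#' Gaussian idle noise. Counts therefore fall when the chest expands, so
#' breath peaks appear as local minima of this stream.
#'
#' @param timeline a [simulate_behavior()] result.
#' @param rip a [rip_params()].
#' @param noise a [noise_spec()].
#' @return 100-Hz `sensor_stream` with channel `pulse_count`.
#' @export
render_rip <- function(timeline, rip = rip_params(), noise = noise_spec()) {
  n <- render_n(timeline$duration_s, 1 / rip$count_window_s)
  rate <- 1 / rip$count_window_s
  circ <- rip$baseline_circumference_cm +
    rip$breath_amplitude_cm * breath_modulation(timeline, rate, 0, n)
  L <- rip$inductance_at(circ)
  f0 <- 1 / (2 * pi * sqrt(L * rip$c_eq_farads))
  if (any(f0 >= 16e6))
    stop("model error: resonant frequency reaches 16 MHz; the counter ",
         "cannot sample it")
  counts <- floor(f0 * rip$count_window_s)
  ns <- noise$rip_count
  if (n > 0 && (ns[1L] != 0 || ns[2L] != 0))
    counts <- counts + with_seed(
      substream_seed(timeline$config$seed, "render_rip"),
      round(stats::rnorm(n, ns[1L], ns[2L])))
  sensor_stream("chest_rip", list(pulse_count = counts), rate_hz = rate,
                units = "count")
}

#' Render the bioimpedance respiration stream
#'
#' Thoracic impedance change rendered as a respiration-synchronous waveform
#' sharing the ground-truth breath peak times with the RIP model (amplitude
#' in mV is arbitrary). Supports windowed rendering for long scenarios.
#'
#' @inheritParams render_rip
#' @param rate_hz sampling rate (1 kHz hardware default).
#' @param amplitude_mv full-depth breath amplitude.
#' @param t_start_s,duration_s window to render (defaults: whole scenario).
#' @return `sensor_stream` with channel `bioimpedance`.
#' @export
render_bioimpedance <- function(timeline, noise = noise_spec(),
                                rate_hz = 1000, amplitude_mv = 1,
                                t_start_s = 0,
                                duration_s = timeline$duration_s - t_start_s) {
  n <- render_n(duration_s, rate_hz)
  x <- amplitude_mv * breath_modulation(timeline, rate_hz, t_start_s, n)
  ns <- noise$bioimpedance_mv
  if (n > 0 && (ns[1L] != 0 || ns[2L] != 0))
    x <- x + with_seed(substream_seed(timeline$config$seed, "render_bioz"),
                       stats::rnorm(n, ns[1L], ns[2L]))
  sensor_stream("chest_bioimpedance", list(bioimpedance = x),
                rate_hz = rate_hz, units = "mV", start_time_s = t_start_s)
}

# beat times by integrating the instantaneous heart-rate profile from t = 0
ecg_beat_times <- function(timeline, until_s) {
  beats <- numeric(ceiling(until_s * 4 / 60 * 60) + 16L)
  k <- 0L; t <- 0.3
  while (t < until_s) {
    k <- k + 1L
    if (k > length(beats)) beats <- c(beats, numeric(length(beats)))
    beats[k] <- t
    t <- t + 60 / hr_at(timeline, t)
  }
  beats[seq_len(k)]
}

#' Render the Lead-I ECG stream
#'
#' Stylized QRS impulse train (Gaussian R-wave template) whose R-R intervals
#' follow the timeline's heart-rate profile, plus 60-Hz power-line
#' interference, slow baseline wander, and idle sensor noise. Only R-peak
#' timing is consumed downstream, so P/T waves are not modelled.
#'
#' @inheritParams render_bioimpedance
#' @param r_amplitude_mv R-wave peak amplitude.
#' @param qrs_sigma_s Gaussian width of the R-wave.
#' @param powerline_mv amplitude of the 60-Hz interference component.
#' @param wander_mv amplitude of the 0.05-Hz baseline wander.
#' @return `sensor_stream` with channel `ecg` in mV.
#' @export
render_ecg <- function(timeline, noise = noise_spec(), rate_hz = 1000,
                       r_amplitude_mv = 1, qrs_sigma_s = 0.012,
                       powerline_mv = 0.05, wander_mv = 0.1,
                       t_start_s = 0,
                       duration_s = timeline$duration_s - t_start_s) {
  if (any(timeline$hr_knots$bpm <= 0))
    stop("model error: non-positive heart rate in profile")
  n <- render_n(duration_s, rate_hz)
  x <- numeric(n)
  beats <- ecg_beat_times(timeline, t_start_s + duration_s)
  beats <- beats[beats > t_start_s - 0.1]
  # Gaussian R wave out to 4 sigma
  for (tb in beats) {
    i0 <- max(1L, ceiling((tb - 4 * qrs_sigma_s - t_start_s) * rate_hz) + 1L)
    i1 <- min(n, floor((tb + 4 * qrs_sigma_s - t_start_s) * rate_hz) + 1L)
    if (i0 > i1) next
    tt <- t_start_s + (seq(i0, i1) - 1) / rate_hz
    x[i0:i1] <- x[i0:i1] +
      r_amplitude_mv * exp(-(tt - tb)^2 / (2 * qrs_sigma_s^2))
  }
  tt <- t_start_s + (seq_len(n) - 1) / rate_hz
  x <- x + powerline_mv * sin(2 * pi * 60 * tt) +
    wander_mv * sin(2 * pi * 0.05 * tt)
  ns <- noise$ecg_mv
  if (n > 0 && (ns[1L] != 0 || ns[2L] != 0))
    x <- x + with_seed(substream_seed(timeline$config$seed, "render_ecg"),
                       stats::rnorm(n, ns[1L], ns[2L]))
  sensor_stream("chest_ecg", list(ecg = x), rate_hz = rate_hz, units = "mV",
                start_time_s = t_start_s)
}

#' Received signal strength of the wrist-to-chest proximity link
#'
#' Inverse-power amplitude-vs-distance law of the 125-kHz RF pair,
#' calibrated so the received amplitude approaches the 2.8-V full scale near
#' contact, stays an order of magnitude above the ~7-mV noise floor at the
#' ~11-cm hand-to-mouth range, and sinks into the noise beyond ~20 cm.
#'
#' @param distance_cm transmitter-receiver distance(s), cm (>= 0).
#' @return amplitude in mV.
#' @export
proximity_amplitude_mv <- function(distance_cm) {
  if (any(distance_cm < 0)) stop("model error: negative distance")
  2800 / (1 + (distance_cm / 4)^3)
}

#' Render the RF proximity stream
#'
#' Baseline receiver noise everywhere; during each puff the received
#' amplitude rises to [proximity_amplitude_mv()] of the puff's
#' transmitter-receiver distance, with short raised-cosine ramps at the puff
#' edges.
#'
#' @inheritParams render_rip
#' @param rate_hz sampling rate (100 Hz hardware default).
#' @return `sensor_stream` with channel `proximity` in mV.
#' @export
render_proximity <- function(timeline, noise = noise_spec(), rate_hz = 100) {
  n <- render_n(timeline$duration_s, rate_hz)
  ns <- noise$proximity_mv
  x <- if (n > 0 && (ns[1L] != 0 || ns[2L] != 0))
    with_seed(substream_seed(timeline$config$seed, "render_prox"),
              stats::rnorm(n, ns[1L], ns[2L]))
  else numeric(n)
  ramp <- 0.3
  for (cg in timeline$cigarettes) {
    p <- cg$puffs
    for (i in seq_len(nrow(p))) {
      amp <- proximity_amplitude_mv(p$tx_rx_distance_cm[i])
      t0p <- p$t_s[i] - ramp; t1p <- p$t_s[i] + p$duration_s[i] + ramp
      i0 <- max(1L, ceiling(t0p * rate_hz) + 1L)
      i1 <- min(n, floor(t1p * rate_hz) + 1L)
      if (i0 > i1) next
      tt <- (seq(i0, i1) - 1) / rate_hz
      env <- pmin(1, pmin((tt - t0p) / ramp, (t1p - tt) / ramp))
      x[i0:i1] <- x[i0:i1] + amp * pmax(env, 0)
    }
  }
  sensor_stream("chest_proximity", list(proximity = x), rate_hz = rate_hz,
                units = "mV")
}

#' Render the instrumented-lighter event log
#'
#' One press/release pair per successful lighting, optionally preceded by
#' repeated rapid presses (failed strikes), plus spurious presses outside
#' any smoking session.
#'
#' @inheritParams render_rip
#' @return `event_log` of `lighter_press` events (press = start,
#'   release = end).
#' @export
render_lighter <- function(timeline) {
  t0 <- numeric(0); t1 <- numeric(0)
  with_seed(substream_seed(timeline$config$seed, "render_lighter"), {
    for (cg in timeline$cigarettes) {
      n_extra <- stats::rgeom(1, 1 - timeline$config$repeat_press_prob)
      offs <- sort(stats::runif(n_extra, 2, 8), decreasing = TRUE)
      press <- c(cg$t_light_s - offs, cg$t_light_s)
      dur <- c(stats::runif(n_extra, 0.3, 1), stats::runif(1, 1.5, 3))
      t0 <- c(t0, press); t1 <- c(t1, press + dur)
    }
    for (ts in timeline$spurious_lighter_presses) {
      t0 <- c(t0, ts); t1 <- c(t1, ts + stats::runif(1, 0.5, 5))
    }
  })
  event_log("lighter", kind = rep("lighter_press", length(t0)),
            t_start_s = t0, t_end_s = t1)
}

#' Render the hand 6-axis IMU stream
#'
#' Accelerometer (g) and gyroscope (dps) channels with idle bias and noise,
#' a large raised-cosine gesture bump spanning each puff (the
#' cigarette-to-mouth wrist movement), and smaller bumps for eating/phone
#' gestures. Values are clipped to the +/-8 g and +/-2000 dps ranges.
#'
#' @inheritParams render_rip
#' @param rate_hz sampling rate (100 Hz).
#' @param puff_bump_g,puff_bump_dps gesture amplitudes at puffs.
#' @param other_bump_g amplitude of non-smoking hand gestures.
#' @return 100-Hz `sensor_stream` with channels ax, ay, az, gx, gy, gz.
#' @export
render_imu_hand <- function(timeline, noise = noise_spec(), rate_hz = 100,
                            puff_bump_g = 1.5, puff_bump_dps = 200,
                            other_bump_g = 0.5) {
  n <- render_n(timeline$duration_s, rate_hz)
  na <- noise$hand_accel_g; ng <- noise$hand_gyro_dps
  ch <- with_seed(substream_seed(timeline$config$seed, "render_imu_hand"), {
    acc <- lapply(1:3, function(i)
      if (na[2L] > 0) stats::rnorm(n, na[1L], na[2L]) else rep(na[1L], n))
    gyr <- lapply(1:3, function(i)
      if (ng[2L] > 0) stats::rnorm(n, ng[1L], ng[2L]) else rep(ng[1L], n))
    pt <- unlist(lapply(timeline$cigarettes,
                        function(cg) cg$puffs$t_s + cg$puffs$duration_s / 2))
    pw <- unlist(lapply(timeline$cigarettes,
                        function(cg) cg$puffs$duration_s / 2 + 1.5))
    if (length(pt)) {
      acc[[1L]] <- add_bumps(acc[[1L]], rate_hz, 0, pt, pw,
                             rep(puff_bump_g, length(pt)))
      gyr[[1L]] <- add_bumps(gyr[[1L]], rate_hz, 0, pt, pw,
                             rep(puff_bump_dps, length(pt)))
    }
    seg <- timeline$segments
    seg <- seg[seg$label %in% c("eating", "phone"), , drop = FALSE]
    for (i in seq_len(nrow(seg))) {
      if (seg$t_end_s[i] - seg$t_start_s[i] < 25) next
      gt <- seq(seg$t_start_s[i] + 10, seg$t_end_s[i] - 10, by = 30)
      if (length(gt))
        acc[[1L]] <- add_bumps(acc[[1L]], rate_hz, 0, gt,
                               rep(1.5, length(gt)),
                               rep(other_bump_g, length(gt)))
    }
    c(acc, gyr)
  })
  ch[1:3] <- lapply(ch[1:3], function(v) pmin(pmax(v, -8), 8))
  ch[4:6] <- lapply(ch[4:6], function(v) pmin(pmax(v, -2000), 2000))
  names(ch) <- c("ax", "ay", "az", "gx", "gy", "gz")
  sensor_stream("hand_imu", ch, rate_hz = rate_hz,
                units = c("g", "g", "g", "dps", "dps", "dps"))
}

#' Render the chest three-axis accelerometer stream
#'
#' Idle bias and noise plus a 2-Hz bounce on the vertical axis during
#' walking segments; clipped to the +/-2 g range.
#'
#' @inheritParams render_imu_hand
#' @return 100-Hz `sensor_stream` with channels ax, ay, az in g.
#' @export
render_chest_accel <- function(timeline, noise = noise_spec(),
                               rate_hz = 100) {
  n <- render_n(timeline$duration_s, rate_hz)
  na <- noise$chest_accel_g
  ch <- with_seed(substream_seed(timeline$config$seed, "render_chest_acc"),
    lapply(1:3, function(i)
      if (na[2L] > 0) stats::rnorm(n, na[1L], na[2L]) else rep(na[1L], n)))
  tt <- (seq_len(n) - 1) / rate_hz
  seg <- timeline$segments
  for (i in seq_len(nrow(seg))) {
    if (seg$label[i] != "walking") next
    idx <- tt >= seg$t_start_s[i] & tt < seg$t_end_s[i]
    ch[[3L]][idx] <- ch[[3L]][idx] + 0.15 * sin(2 * pi * 2 * tt[idx])
  }
  ch <- lapply(ch, function(v) pmin(pmax(v, -2), 2))
  names(ch) <- c("ax", "ay", "az")
  sensor_stream("chest_accel", ch, rate_hz = rate_hz, units = "g")
}

#' Render the GPS fix stream
#'
#' Fixes follow the route displaced by a random draw whose distance has the
#' idle-test mean/sd (bearing uniform). Indoors the receiver loses the
#' satellites and keeps logging its last received coordinates; set
#' `indoor_hold = FALSE` to model open-sky reception everywhere (as in the
#' static bench test).
#'
#' @inheritParams render_rip
#' @param rate_hz fix rate (1 Hz).
#' @param indoor_hold hold the last outdoor fix during indoor segments.
#' @return `sensor_stream` with channels latitude_deg, longitude_deg.
#' @export
render_gps <- function(timeline, noise = noise_spec(), rate_hz = 1,
                       indoor_hold = TRUE) {
  n <- render_n(timeline$duration_s, rate_hz)
  tt <- (seq_len(n) - 1) / rate_hz
  r <- timeline$route
  if (!nrow(r)) {
    lat0 <- rep(timeline$config$home_lat_deg, n)
    lon0 <- rep(timeline$config$home_lon_deg, n)
    outdoor <- rep(!indoor_hold, n)
  } else {
    lat0 <- stats::approx(r$t_s, r$lat_deg, xout = tt, rule = 2)$y
    lon0 <- stats::approx(r$t_s, r$lon_deg, xout = tt, rule = 2)$y
    outdoor <- if (indoor_hold)
      as.logical(stats::approx(r$t_s, as.numeric(r$outdoor), xout = tt,
                               method = "constant", rule = 2)$y)
    else rep(TRUE, n)
  }
  ns <- noise$gps_m
  with_seed(substream_seed(timeline$config$seed, "render_gps"), {
    dist_m <- pmax(stats::rnorm(n, ns[1L], ns[2L]), 0)
    bear <- stats::runif(n, 0, 2 * pi)
  })
  lat <- lat0 + dist_m * cos(bear) / 111320
  lon <- lon0 + dist_m * sin(bear) / (111320 * cos(lat0 * pi / 180))
  # indoors: repeat the last received (outdoor) fix verbatim
  recv <- outdoor | c(TRUE, rep(FALSE, max(n - 1L, 0L)))
  if (n > 0L && !all(recv)) {
    last <- cummax(ifelse(recv, seq_len(n), 0L))
    lat <- lat[last]; lon <- lon[last]
  }
  sensor_stream("chest_gps",
                list(latitude_deg = lat, longitude_deg = lon),
                rate_hz = rate_hz, units = "degrees")
}

#' Render the pedometer event log
#'
#' The step counter buffers for 13.63 s and then logs the window's total; the
#' rendered log is one `pedometer_window` event per buffer with a
#' `step_count` attribute.
#'
#' @inheritParams render_rip
#' @return `event_log` of `pedometer_window` events.
#' @export
render_pedometer <- function(timeline) {
  s <- timeline$steps
  event_log("hand_pedometer",
            kind = rep("pedometer_window", nrow(s)),
            t_start_s = s$window_start_s,
            t_end_s = pmin(s$window_start_s + 13.63, timeline$duration_s),
            attrs = lapply(s$count, function(k) list(step_count = k)))
}

#' Inject clock drift into a stream or event log
#'
#' Maps true timestamps to the drifting device clock,
#' `t = t0 + f * (t_true - t0)`: the exact inverse of the linear
#' compensation applied by [compensate()]. For streams the start time is
#' mapped and the sampling rate divided by `f` (the within-file rate error
#' is the same linear factor).
#'
#' @param x a `sensor_stream` or `event_log`.
#' @param clock a [clock_model()].
#' @return object of the same class with device-clock timestamps.
#' @export
apply_clock_drift <- function(x, clock) {
  stopifnot(inherits(clock, "clock_model"))
  if (clock$f <= 0) stop("model error: correction factor f must be > 0")
  warp <- function(t) clock$t0_s + clock$f * (t - clock$t0_s)
  if (inherits(x, "sensor_stream")) {
    x$start_time_s <- warp(x$start_time_s)
    x$rate_hz <- x$rate_hz / clock$f
    x
  } else if (inherits(x, "event_log")) {
    x$events$t_start_s <- warp(x$events$t_start_s)
    x$events$t_end_s <- warp(x$events$t_end_s)
    x
  } else stop("apply_clock_drift: unsupported type")
}
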