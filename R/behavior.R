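# Ground-truth behavior generation: what the wearer actually did, before any
# sensor sees it. Renders (render_*.R) turn this into raw device streams.

with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else suppressWarnings(rm(".Random.seed", envir = globalenv()))
  })
  set.seed(seed)
  expr
}

# deterministic per-render substream: same timeline seed + tag -> same draws
substream_seed <- function(seed, tag) {
  v <- as.numeric(utf8ToInt(tag))
  h <- sum(v * seq_along(v) * 2654435) %% 2147483647
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483647)
}

#' Simulation scenario configuration
#'
#' Parameters of the virtual smoker: smoking rate and topography, breathing
#' and heart-rate processes, walking, spurious lighter activity and
#' per-device clock drift. Defaults follow the 40-subject validation-study
#' statistics (about 11 self-reported cigarettes/day; sitting-smoking heart
#' rate near 112 bpm vs. a pre-smoking baseline near 81.5 bpm with recovery
#' to baseline within 15 min) and typical resting respiration of 12-20
#' breaths/min.
#'
#' @param seed integer; fixes every downstream draw (behavior and renders).
#' @param duration_s scenario length in seconds (default one day).
#' @param cigarettes_per_day expected daily cigarette count (Poisson).
#' @param puffs_per_cigarette_mean expected puffs per cigarette (Poisson,
#'   floored at 3).
#' @param cigarette_duration_s min/max cigarette duration (s).
#' @param puff_duration_s min/max single-puff inhalation duration (s).
#' @param puff_distance_cm min/max transmitter-receiver distance during a
#'   puff (cm); must stay below 15 cm, within sensor reach (~11 cm typical).
#' @param breath_rate_range_bpm resting breathing-rate band (breaths/min).
#' @param breath_depth_range relative breath depth band (fraction 0-1).
#' @param hr_baseline_bpm,hr_smoking_bpm,hr_post_bpm mean heart rate at
#'   baseline, during smoking, and immediately post-smoking.
#' @param hr_recovery_s time to return to baseline after a cigarette (s).
#' @param repeat_press_prob probability of each extra lighter press before
#'   the successful lighting press.
#' @param spurious_press_rate_per_day expected daily rate of lighter presses
#'   outside any smoking session.
#' @param walk_fraction fraction of (non-smoking) time spent walking.
#' @param step_cadence_per_min walking cadence (steps/min).
#' @param drift_s_per_day named numeric: per-device clock drift in seconds
#'   gained (+) or lost (-) per day, "up to several seconds per day".
#' @param home_lat_deg,home_lon_deg anchor coordinate of the route (WGS-84).
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       duration_s = 86400,
                       cigarettes_per_day = 11,
                       puffs_per_cigarette_mean = 10,
                       cigarette_duration_s = c(240, 420),
                       puff_duration_s = c(1.5, 3),
                       puff_distance_cm = c(5, 11),
                       breath_rate_range_bpm = c(12, 20),
                       breath_depth_range = c(0.5, 1),
                       hr_baseline_bpm = 81.5,
                       hr_smoking_bpm = 112,
                       hr_post_bpm = 89.7,
                       hr_recovery_s = 900,
                       repeat_press_prob = 0.3,
                       spurious_press_rate_per_day = 0.5,
                       walk_fraction = 0.15,
                       step_cadence_per_min = 100,
                       drift_s_per_day = c(lighter = 2, hand = -3, chest = 5),
                       home_lat_deg = 40.0, home_lon_deg = -75.0) {
  if (!is.numeric(duration_s) || length(duration_s) != 1L || duration_s < 0)
    stop("config error: duration_s must be a non-negative scalar")
  if (max(puff_distance_cm) > 15)
    stop("config error: puff distances must stay below 15 cm")
  if (hr_baseline_bpm <= 0 || hr_smoking_bpm <= 0 || hr_post_bpm <= 0)
    stop("config error: heart rates must be positive")
  structure(as.list(environment()), class = "sim_config")
}

#' Simulate a ground-truth behavior timeline
#'
#' Draws one realization of the virtual smoker: breath times and depths,
#' cigarettes with their puffs (times, durations, hand-to-mouth distances),
#' spurious lighter presses, pedometer step windows (13.63-s buffers),
#' a piecewise-linear heart-rate profile that rises during each cigarette
#' and decays back to baseline within the recovery window, a walking route,
#' and activity segments. Everything is deterministic given `config$seed`.
#'
#' @param config a [sim_config()].
#' @return An object of class `behavior_timeline` with elements `breaths`
#'   (data frame `peak_time_s`, `depth`), `cigarettes` (list; each has
#'   `t_light_s`, `t_end_s` and a `puffs` data frame with `t_s`,
#'   `duration_s`, `tx_rx_distance_cm`), `spurious_lighter_presses`
#'   (numeric), `steps` (data frame `window_start_s`, `count`), `hr_knots`
#'   (piecewise-linear profile), `route`, `segments` and `duration_s`.
#' @examples
#' tl <- simulate_behavior(sim_config(seed = 7, duration_s = 3600,
#'                                    cigarettes_per_day = 24))
#' length(tl$cigarettes)
#' @export
simulate_behavior <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  dur <- config$duration_s
  if (dur == 0) {
    return(structure(
      list(duration_s = 0,
           breaths = data.frame(peak_time_s = numeric(), depth = numeric()),
           cigarettes = list(), spurious_lighter_presses = numeric(),
           steps = data.frame(window_start_s = numeric(), count = integer()),
           hr_knots = data.frame(t_s = 0, bpm = config$hr_baseline_bpm),
           route = data.frame(t_s = numeric(), lat_deg = numeric(),
                              lon_deg = numeric(), outdoor = logical()),
           segments = data.frame(t_start_s = numeric(), t_end_s = numeric(),
                                 label = character()),
           config = config),
      class = "behavior_timeline"))
  }
  with_seed(substream_seed(config$seed, "behavior"), {
    ## activity segments (~20 min each)
    seg_b <- 0
    while (sum(seg_b[length(seg_b)]) < dur)
      seg_b <- c(seg_b, seg_b[length(seg_b)] + stats::runif(1, 600, 1800))
    seg_b[length(seg_b)] <- dur
    seg_b <- unique(seg_b)
    nseg <- length(seg_b) - 1L
    labs <- sample(c("walking", "sitting", "standing", "eating", "phone"),
                   nseg, replace = TRUE,
                   prob = c(config$walk_fraction,
                            rep((1 - config$walk_fraction) / 4, 4)))
    segments <- data.frame(t_start_s = seg_b[-length(seg_b)],
                           t_end_s = seg_b[-1L], label = labs,
                           stringsAsFactors = FALSE)

    ## cigarettes: Poisson count, non-overlapping sessions
    n_cig <- stats::rpois(1, config$cigarettes_per_day * dur / 86400)
    cigarettes <- list()
    if (n_cig > 0) {
      durs <- stats::runif(n_cig, config$cigarette_duration_s[1L],
                           config$cigarette_duration_s[2L])
      starts <- sort(stats::runif(n_cig, 0, max(dur - max(durs), 1)))
      keep <- rep(TRUE, n_cig); last_end <- -Inf
      for (i in seq_len(n_cig)) {  # enforce >= 10 min between sessions
        if (starts[i] < last_end + 600) keep[i] <- FALSE
        else last_end <- starts[i] + durs[i]
      }
      starts <- starts[keep]; durs <- durs[keep]
      cigarettes <- lapply(seq_along(starts), function(i) {
        t0 <- starts[i]; t1 <- min(starts[i] + durs[i], dur)
        k <- max(3L, stats::rpois(1, config$puffs_per_cigarette_mean))
        lo <- t0 + 10; hi <- max(t1 - 10, lo + 1)
        pt <- sort(lo + (hi - lo) *
                     (seq_len(k) - stats::runif(k, 0.1, 0.9)) / k)
        list(t_light_s = t0, t_end_s = t1,
             puffs = data.frame(
               t_s = pt,
               duration_s = stats::runif(k, config$puff_duration_s[1L],
                                         config$puff_duration_s[2L]),
               tx_rx_distance_cm = stats::runif(
                 k, config$puff_distance_cm[1L], config$puff_distance_cm[2L])))
      })
    }

    ## breaths: renewal process, rate redrawn every minute within band
    bt <- numeric(0); t <- stats::runif(1, 2, 5)
    rate <- stats::runif(1, config$breath_rate_range_bpm[1L],
                         config$breath_rate_range_bpm[2L])
    next_redraw <- 60
    while (t < dur) {
      bt <- c(bt, t)
      if (t > next_redraw) {
        rate <- stats::runif(1, config$breath_rate_range_bpm[1L],
                             config$breath_rate_range_bpm[2L])
        next_redraw <- next_redraw + 60
      }
      t <- t + (60 / rate) * stats::runif(1, 0.9, 1.1)
    }
    breaths <- data.frame(
      peak_time_s = bt,
      depth = stats::runif(length(bt), config$breath_depth_range[1L],
                           config$breath_depth_range[2L]))

    ## spurious lighter presses, outside all smoking sessions
    in_session <- function(t)
      any(vapply(cigarettes, function(cg)
        t >= cg$t_light_s & t <= cg$t_end_s, logical(1)))
    n_sp <- stats::rpois(1, config$spurious_press_rate_per_day * dur / 86400)
    spurious <- numeric(0)
    while (length(spurious) < n_sp) {
      cand <- stats::runif(1, 0, dur)
      if (length(cigarettes) == 0L || !in_session(cand))
        spurious <- c(spurious, cand)
    }
    spurious <- sort(spurious)

    ## pedometer windows (13.63-s processor buffer)
    ws <- seq(0, dur, by = 13.63)
    ws <- ws[ws < dur]
    mid <- ws + 13.63 / 2
    seg_of <- findInterval(pmin(mid, dur - 1e-9), seg_b,
                           rightmost.closed = TRUE)
    walking <- segments$label[pmax(seg_of, 1L)] == "walking"
    counts <- integer(length(ws))
    counts[walking] <- pmax(0L, as.integer(round(
      config$step_cadence_per_min * 13.63 / 60 *
        stats::runif(sum(walking), 0.85, 1.15))))
    steps <- data.frame(window_start_s = ws, count = counts)

    ## heart-rate profile: baseline, smoking elevation, post decay
    kt <- 0; kb <- config$hr_baseline_bpm
    for (cg in cigarettes) {
      t0 <- cg$t_light_s; t1 <- cg$t_end_s
      pts <- c(t0, t0 + 60, t1, t1 + config$hr_recovery_s / 3,
               t1 + config$hr_recovery_s)
      bpm <- c(config$hr_baseline_bpm, config$hr_smoking_bpm,
               config$hr_smoking_bpm, config$hr_post_bpm,
               config$hr_baseline_bpm)
      ok <- pts > kt[length(kt)]
      kt <- c(kt, pts[ok]); kb <- c(kb, bpm[ok])
    }
    if (kt[length(kt)] < dur) { kt <- c(kt, dur); kb <- c(kb, kb[length(kb)]) }
    hr_knots <- data.frame(t_s = kt, bpm = kb)

    ## route: move at ~1.4 m/s during (outdoor) walking segments
    rt <- seq(0, dur, by = 5)
    lat <- rep(config$home_lat_deg, length(rt))
    lon <- rep(config$home_lon_deg, length(rt))
    outdoor <- logical(length(rt))
    heading <- stats::runif(1, 0, 2 * pi)
    for (i in seq_along(rt)[-1L]) {
      si <- findInterval(rt[i], seg_b, rightmost.closed = TRUE)
      if (si >= 1L && si <= nseg && segments$label[si] == "walking") {
        heading <- heading + stats::rnorm(1, 0, 0.15)
        step_m <- 1.4 * 5
        lat[i] <- lat[i - 1L] + step_m * cos(heading) / 111320
        lon[i] <- lon[i - 1L] + step_m * sin(heading) /
          (111320 * cos(lat[i - 1L] * pi / 180))
        outdoor[i] <- TRUE
      } else {
        lat[i] <- lat[i - 1L]; lon[i] <- lon[i - 1L]
      }
    }
    route <- data.frame(t_s = rt, lat_deg = lat, lon_deg = lon,
                        outdoor = outdoor)

    tl <- structure(
      list(duration_s = dur, breaths = breaths, cigarettes = cigarettes,
           spurious_lighter_presses = spurious, steps = steps,
           hr_knots = hr_knots, route = route, segments = segments,
           config = config),
      class = "behavior_timeline")
    validate_timeline(tl)
    tl
  })
}

validate_timeline <- function(tl) {
  if (nrow(tl$breaths) > 1L && any(diff(tl$breaths$peak_time_s) <= 0))
    stop("timeline invariant violated: breath times not strictly increasing")
  if (any(tl$hr_knots$bpm <= 0))
    stop("timeline invariant violated: non-positive heart rate")
  for (cg in tl$cigarettes) {
    if (nrow(cg$puffs) &&
        (any(cg$puffs$t_s < cg$t_light_s) || any(cg$puffs$t_s > cg$t_end_s)))
      stop("timeline invariant violated: puff outside its cigarette")
    if (any(cg$puffs$tx_rx_distance_cm > 15))
      stop("timeline invariant violated: puff distance above 15 cm")
  }
  invisible(tl)
}

#' @export
print.behavior_timeline <- function(x, ...) {
  cat(sprintf(paste0("<behavior_timeline> %.0f s: %d breaths, %d cigarettes",
                     " (%d puffs), %d spurious presses, %d steps\n"),
              x$duration_s, nrow(x$breaths), length(x$cigarettes),
              total_puffs(x), length(x$spurious_lighter_presses),
              sum(x$steps$count)))
  invisible(x)
}

#' Query helpers for a behavior timeline
#'
#' `hr_at()` evaluates the piecewise-linear heart-rate profile; `total_puffs()`
#' counts ground-truth puffs across all cigarettes.
#'
#' @param timeline a `behavior_timeline`.
#' @param t_s time(s) in seconds.
#' @export
hr_at <- function(timeline, t_s) {
  k <- timeline$hr_knots
  if (nrow(k) == 1L) return(rep(k$bpm, length(t_s)))
  stats::approx(k$t_s, k$bpm, xout = t_s, rule = 2)$y
}

#' @rdname hr_at
#' @export
total_puffs <- function(timeline)
  sum(vapply(timeline$cigarettes, function(cg) nrow(cg$puffs), integer(1)))
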