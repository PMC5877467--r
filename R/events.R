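# Reduction of conditioned streams and raw logs to behavioral and
# physiological events: breaths, R-peaks, hand-to-mouth proximity,
# cigarette consolidation, usability screening, step counting.

#' Detection parameters
#'
#' Tunable parameters of the event detectors. The proximity threshold
#' defaults to ten times the configured receiver noise mean (7 mV -> 70 mV).
#'
#' @param proximity_noise_mean_mv receiver noise mean used to derive the
#'   detection threshold.
#' @param proximity_threshold_mv amplitude threshold for a valid
#'   hand-to-mouth proximity movement (default `10 * proximity_noise_mean_mv`).
#' @param min_breath_interval_s minimum spacing between accepted breath
#'   peaks (default 1 s, capping breathing at 60/min).
#' @param min_breath_prominence_frac prominence floor for breath peaks, as a
#'   fraction of the signal interquartile range.
#' @param min_rr_interval_s minimum R-R interval (refractory period).
#' @param rpeak_height_frac R-peak height floor, as a fraction of the
#'   median-to-99.9th-percentile amplitude span.
#' @param lighter_merge_window_s presses within this window before a smoking
#'   session's start (or separated by less than this within a session) are
#'   grouped into one lighting.
#' @param proximity_merge_gap_s above-threshold runs closer than this merge
#'   into one proximity event.
#' @param flatline_window_s usability-screening window length.
#' @param flatline_sd_floor named numeric: per-channel standard-deviation
#'   floor below which a window is flat (defaults: 3x the idle noise sd of
#'   the RIP counter, and a small absolute floor for the bioimpedance
#'   channel whose idle noise is nominally zero).
#' @return An object of class `detection_params`.
#' @export
detection_params <- function(proximity_noise_mean_mv = 7,
                             proximity_threshold_mv =
                               10 * proximity_noise_mean_mv,
                             min_breath_interval_s = 1.0,
                             min_breath_prominence_frac = 0.1,
                             min_rr_interval_s = 0.3,
                             rpeak_height_frac = 0.5,
                             lighter_merge_window_s = 60,
                             proximity_merge_gap_s = 0.5,
                             flatline_window_s = 60,
                             flatline_sd_floor = c(rip = 3 * 1.29,
                                                   bioimpedance = 0.01)) {
  p <- list(proximity_noise_mean_mv = proximity_noise_mean_mv,
            proximity_threshold_mv = proximity_threshold_mv,
            min_breath_interval_s = min_breath_interval_s,
            min_breath_prominence_frac = min_breath_prominence_frac,
            min_rr_interval_s = min_rr_interval_s,
            rpeak_height_frac = rpeak_height_frac,
            lighter_merge_window_s = lighter_merge_window_s,
            proximity_merge_gap_s = proximity_merge_gap_s,
            flatline_window_s = flatline_window_s,
            flatline_sd_floor = flatline_sd_floor)
  num <- unlist(p[names(p) != "flatline_sd_floor"])
  if (any(num <= 0) || any(flatline_sd_floor <= 0))
    stop("all detection parameters must be positive")
  structure(p, class = "detection_params")
}

#' Local-maxima finder with prominence and minimum-distance filtering
#'
#' Finds strict local maxima, drops any peak within `min_dist` samples of a
#' higher accepted peak (highest peaks retained first), and drops peaks
#' whose topographic prominence (height above the higher of the two valley
#' minima separating it from taller terrain) falls below `min_prominence`.
#'
#' @param x numeric vector.
#' @param min_dist minimum peak separation, in samples.
#' @param min_prominence prominence floor, in signal units.
#' @return integer vector of peak indices, increasing.
#' @export
find_peaks <- function(x, min_dist = 1, min_prominence = 0) {
  n <- length(x)
  if (n < 3L) return(integer(0))
  # candidate maxima, vectorized; plateaus contribute their first sample
  s <- sign(diff(x))
  nz <- which(s != 0)
  if (length(nz) < 2L) return(integer(0))
  sv <- s[nz]
  trans <- which(sv[-length(sv)] > 0 & sv[-1L] < 0)
  cand <- nz[trans] + 1L
  if (!length(cand)) return(integer(0))
  # minimum-distance suppression: highest peaks claim their neighbourhood
  if (min_dist > 1 && length(cand) > 1L) {
    d <- as.integer(ceiling(min_dist))
    covered <- logical(n)
    keep <- logical(length(cand))
    for (j in order(-x[cand], cand)) {
      i <- cand[j]
      if (!covered[i]) {
        keep[j] <- TRUE
        covered[max(1L, i - d + 1L):min(n, i + d - 1L)] <- TRUE
      }
    }
    cand <- cand[keep]
  }
  # prominence on the surviving peak/valley skeleton: valleys are the true
  # sample minima between consecutive survivors (and out to each edge)
  if (min_prominence > 0 && length(cand)) {
    k <- length(cand)
    h <- x[cand]
    vall <- numeric(k + 1L)
    vall[1L] <- min(x[1L:cand[1L]])
    vall[k + 1L] <- min(x[cand[k]:n])
    if (k > 1L)
      vall[2L:k] <- vapply(seq_len(k - 1L), function(i)
        min(x[cand[i]:cand[i + 1L]]), numeric(1))
    prom <- numeric(k)
    for (i in seq_len(k)) {
      lref <- vall[i]; j <- i - 1L
      while (j >= 1L && h[j] <= h[i]) { lref <- min(lref, vall[j]); j <- j - 1L }
      rref <- vall[i + 1L]; j <- i + 1L
      while (j <= k && h[j] <= h[i]) { rref <- min(rref, vall[j + 1L]); j <- j + 1L }
      prom[i] <- h[i] - max(lref, rref)
    }
    cand <- cand[prom >= min_prominence]
  }
  cand
}

stream_channel <- function(stream, chan = 1L) stream$samples[[chan]]

#' Detect breaths on a conditioned respiration stream
#'
#' One `detected_breath` event per accepted local maximum. Peaks closer than
#' `min_breath_interval_s` or with prominence below
#' `min_breath_prominence_frac` of the signal IQR are rejected. The RIP
#' pulse-count stream falls when the chest expands, so pass `invert = TRUE`
#' for it; the bioimpedance waveform peaks with the breath directly.
#'
#' @param stream conditioned respiration `sensor_stream`
#'   ([condition()] with kind `"rip"` or `"bioimpedance"`).
#' @param params a [detection_params()].
#' @param invert negate the signal before peak finding.
#' @return `event_log` of zero-duration `detected_breath` events.
#' @export
detect_breaths <- function(stream, params = detection_params(),
                           invert = FALSE) {
  x <- stream_channel(stream)
  if (invert) x <- -x
  if (length(x) == 0L) return(event_log(stream$device_id))
  iqr <- stats::IQR(x)
  pk <- find_peaks(x,
                   min_dist = params$min_breath_interval_s * stream$rate_hz,
                   min_prominence = params$min_breath_prominence_frac * iqr)
  t <- stream_times(stream)[pk]
  event_log(stream$device_id, kind = rep("detected_breath", length(pk)),
            t_start_s = t)
}

#' Detect R-peaks on a conditioned ECG stream
#'
#' Local maxima with a refractory minimum R-R interval and a height floor
#' relative to the signal's amplitude span (median to 99.9th percentile),
#' robust to the near-zero baseline between QRS complexes.
#'
#' @param stream conditioned ECG `sensor_stream` ([condition()] kind
#'   `"ecg"`).
#' @param params a [detection_params()].
#' @return `event_log` of zero-duration `detected_rpeak` events.
#' @export
detect_rpeaks <- function(stream, params = detection_params()) {
  x <- stream_channel(stream)
  if (length(x) == 0L) return(event_log(stream$device_id))
  floor_h <- stats::median(x) + params$rpeak_height_frac *
    (stats::quantile(x, 0.999, names = FALSE) - stats::median(x))
  pk <- find_peaks(x, min_dist = params$min_rr_interval_s * stream$rate_hz)
  pk <- pk[x[pk] >= floor_h]
  event_log(stream$device_id, kind = rep("detected_rpeak", length(pk)),
            t_start_s = stream_times(stream)[pk])
}

#' Instantaneous heart rate from an R-peak log
#'
#' `60 / RR` for each R-R interval, assigned to the interval midpoint.
#'
#' @param rpeaks an `event_log` of `detected_rpeak` events.
#' @return data frame with `t_s` (midpoints) and `hr_bpm`.
#' @export
instantaneous_hr <- function(rpeaks) {
  t <- rpeaks$events$t_start_s
  if (length(t) < 2L)
    return(data.frame(t_s = numeric(), hr_bpm = numeric()))
  rr <- diff(t)
  data.frame(t_s = t[-length(t)] + rr / 2, hr_bpm = 60 / rr)
}

#' Heart-rate summary around a smoking session
#'
#' Mean and sd of the instantaneous heart rate (60/RR at interval midpoints)
#' within the session, the 5 min preceding it and the 15 min following it.
#'
#' @param rpeaks an `event_log` of `detected_rpeak` events.
#' @param session numeric `c(t_start_s, t_end_s)` of the smoking session.
#' @param pre_s,post_s lengths of the pre/post comparison windows (s).
#' @return object of class `hr_summary`: data frame with one row per window
#'   (`smoking`, `pre`, `post`) and columns `mean_bpm`, `sd_bpm`, `n_beats`.
#' @export
summarize_heart_rate <- function(rpeaks, session, pre_s = 300,
                                 post_s = 900) {
  stopifnot(length(session) == 2L, session[2L] > session[1L])
  hr <- instantaneous_hr(rpeaks)
  win <- list(smoking = session,
              pre = c(session[1L] - pre_s, session[1L]),
              post = c(session[2L], session[2L] + post_s))
  rows <- lapply(names(win), function(nm) {
    w <- win[[nm]]
    inw <- hr$t_s >= w[1L] & hr$t_s <= w[2L]
    npk <- sum(rpeaks$events$t_start_s >= w[1L] &
                 rpeaks$events$t_start_s <= w[2L])
    if (npk < 2L)
      stop("undefined-HR error: window '", nm, "' contains ", npk,
           " R-peak(s); at least 2 required")
    data.frame(window = nm, mean_bpm = mean(hr$hr_bpm[inw]),
               sd_bpm = stats::sd(hr$hr_bpm[inw]), n_beats = npk,
               stringsAsFactors = FALSE)
  })
  structure(do.call(rbind, rows), class = c("hr_summary", "data.frame"))
}

#' Detect hand-to-mouth proximity events
#'
#' A valid hand-to-mouth proximity movement is a maximal run of samples with
#' amplitude above the threshold (default 70 mV, ten times the 7-mV receiver
#' noise mean); runs separated by less than `proximity_merge_gap_s` are
#' merged into one event.
#'
#' @param stream conditioned proximity `sensor_stream`, in mV.
#' @param params a [detection_params()].
#' @return `event_log` of `detected_proximity` events (one per movement).
#' @export
detect_proximity_events <- function(stream, params = detection_params()) {
  x <- stream_channel(stream)
  above <- x > params$proximity_threshold_mv
  if (!any(above)) return(event_log(stream$device_id))
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- data.frame(i0 = starts[r$values], i1 = ends[r$values])
  # merge runs separated by a short sub-threshold gap
  gap_n <- params$proximity_merge_gap_s * stream$rate_hz
  merged <- runs[1L, , drop = FALSE]
  for (k in seq_len(nrow(runs))[-1L]) {
    if (runs$i0[k] - merged$i1[nrow(merged)] - 1L < gap_n)
      merged$i1[nrow(merged)] <- runs$i1[k]
    else merged <- rbind(merged, runs[k, ])
  }
  tt <- stream_times(stream)
  event_log(stream$device_id,
            kind = rep("detected_proximity", nrow(merged)),
            t_start_s = tt[merged$i0], t_end_s = tt[merged$i1])
}

#' Consolidate lighter presses into cigarette estimates
#'
#' Presses falling inside a smoking session, or within
#' `lighter_merge_window_s` before its start, belong to that session;
#' within a session, consecutive presses separated by at most the merge
#' window collapse into one lighting (repeated strikes before the cigarette
#' lights). Presses covered by no session are discarded and reported as
#' false lighting events.
#'
#' @param lighter an `event_log` of `lighter_press` events (compensated
#'   clock).
#' @param sessions an `event_log` of smoking sessions
#'   (`self_report_cigarette` events, compensated clock); must not overlap.
#' @param params a [detection_params()].
#' @return list of class `lighter_consolidation`: `cigarettes` (an
#'   `event_log` of `cigarette_estimate` events), `n_false_events`,
#'   `n_presses`, `n_grouped_presses`.
#' @export
consolidate_lighter <- function(lighter, sessions,
                                params = detection_params()) {
  se <- sessions$events
  if (nrow(se) > 1L &&
      any(se$t_start_s[-1L] < se$t_end_s[-nrow(se)] - 1e-9))
    stop("integrity error: overlapping self-report sessions")
  press <- lighter$events$t_start_s
  w <- params$lighter_merge_window_s
  sess_of <- rep(NA_integer_, length(press))
  for (j in seq_len(nrow(se))) {
    inj <- press >= se$t_start_s[j] - w & press <= se$t_end_s[j]
    sess_of[inj & is.na(sess_of)] <- j
  }
  n_false <- sum(is.na(sess_of))
  cg_t0 <- numeric(0); cg_t1 <- numeric(0); cg_attr <- list()
  for (j in unique(sess_of[!is.na(sess_of)])) {
    pt <- sort(press[which(sess_of == j)])
    grp_start <- c(TRUE, diff(pt) > w)
    gid <- cumsum(grp_start)
    for (g in unique(gid)) {
      tg <- pt[gid == g]
      cg_t0 <- c(cg_t0, tg[1L]); cg_t1 <- c(cg_t1, tg[length(tg)])
      cg_attr <- c(cg_attr, list(list(n_presses = length(tg), session = j)))
    }
  }
  structure(
    list(cigarettes = event_log(
           lighter$device_id,
           kind = rep("cigarette_estimate", length(cg_t0)),
           t_start_s = cg_t0, t_end_s = cg_t1, attrs = cg_attr),
         n_false_events = n_false,
         n_presses = length(press),
         n_grouped_presses = length(press) - n_false),
    class = "lighter_consolidation")
}

#' @export
print.lighter_consolidation <- function(x, ...) {
  cat(sprintf(paste0("<lighter_consolidation> %d presses -> %d cigarettes",
                     " (%d false lighting events discarded)\n"),
              x$n_presses, n_events(x$cigarettes), x$n_false_events))
  invisible(x)
}

#' Screen recording usability from respiration channels
#'
#' Sliding-window standard-deviation test on the two respiration streams
#' (clock-compensated). Windows where both channels fall below their
#' flatline floors are `removed` (device off body / no valid signal);
#' windows where exactly one respiration sensor shows signal are
#' `ambiguous`; the rest are `usable`.
#'
#' @param rip,bioz conditioned RIP and bioimpedance `sensor_stream`s
#'   covering the same recording.
#' @param params a [detection_params()].
#' @return a [usability_mask()] tiling the recording at
#'   `flatline_window_s` resolution.
#' @export
screen_usability <- function(rip, bioz, params = detection_params()) {
  dur <- min(n_samples(rip) / rip$rate_hz, n_samples(bioz) / bioz$rate_hz)
  wlen <- params$flatline_window_s
  n_win <- max(1L, ceiling(dur / wlen))
  win_sd <- function(stream, i) {
    t0 <- (i - 1L) * wlen; t1 <- min(i * wlen, dur)
    i0 <- floor((t0 - stream$start_time_s) * stream$rate_hz) + 1L
    i1 <- min(n_samples(stream),
              ceiling((t1 - stream$start_time_s) * stream$rate_hz))
    if (i1 <= i0) return(0)
    stats::sd(stream_channel(stream)[i0:i1])
  }
  floors <- params$flatline_sd_floor
  lab <- vapply(seq_len(n_win), function(i) {
    a <- win_sd(rip, i) >= floors[["rip"]]
    b <- win_sd(bioz, i) >= floors[["bioimpedance"]]
    if (a && b) "usable" else if (!a && !b) "removed" else "ambiguous"
  }, character(1))
  t0 <- (seq_len(n_win) - 1L) * wlen
  usability_mask(t0, pmin(t0 + wlen, dur), lab)
}

#' Count steps over an interval
#'
#' Sums pedometer window counts over all buffers overlapping the interval,
#' prorating buffers that only partially overlap.
#'
#' @param pedometer an `event_log` of `pedometer_window` events with a
#'   `step_count` attribute.
#' @param interval numeric `c(t_start_s, t_end_s)`.
#' @return estimated step count (numeric; fractional when prorated).
#' @export
count_steps <- function(pedometer, interval) {
  stopifnot(length(interval) == 2L)
  if (interval[2L] <= interval[1L]) return(0)
  ev <- pedometer$events
  counts <- vapply(pedometer$attrs, function(a)
    as.numeric(a$step_count %||% 0), numeric(1))
  ov <- pmax(0, pmin(ev$t_end_s, interval[2L]) -
                pmax(ev$t_start_s, interval[1L]))
  frac <- ifelse(ev$t_end_s > ev$t_start_s,
                 ov / (ev$t_end_s - ev$t_start_s), 0)
  sum(counts * frac)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Count hand-to-mouth gestures from the hand IMU
#'
#' Pluggable interface for an IMU gesture classifier. The default detector
#' is a documented simple placeholder: runs where the low-pass-conditioned
#' first accelerometer channel deviates from its median by more than
#' `threshold_g`, merged across gaps shorter than `merge_gap_s`, each count
#' as one gesture. Replace `detector` with a real classifier for production
#' use.
#'
#' @param stream conditioned hand-IMU `sensor_stream`
#'   ([condition()] kind `"imu"`).
#' @param detector `NULL` for the placeholder, or a
#'   `function(stream) -> integer`.
#' @param threshold_g,merge_gap_s placeholder parameters.
#' @return integer gesture count.
#' @export
count_h2m_from_imu <- function(stream, detector = NULL, threshold_g = 1,
                               merge_gap_s = 1) {
  if (!is.null(detector)) return(as.integer(detector(stream)))
  x <- stream_channel(stream)
  if (!length(x)) return(0L)
  above <- abs(x - stats::median(x)) > threshold_g
  if (!any(above)) return(0L)
  r <- rle(above)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  i0 <- starts[r$values]; i1 <- ends[r$values]
  gap_n <- merge_gap_s * stream$rate_hz
  if (length(i0) < 2L) return(length(i0))
  new_run <- c(TRUE, i0[-1L] - i1[-length(i1)] - 1L >= gap_n)
  as.integer(sum(new_run))
}
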