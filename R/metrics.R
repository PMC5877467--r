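# Bench-test computations and study-level summaries: Table-style event
# bookkeeping per study portion, sensor agreement, great-circle GPS
# displacement, and the LC resonance physics of the respiration belt.

#' Study-level summary report
#'
#' Builds the per-portion event-count table (controlled portion, free-living
#' portion, total) together with the usable-data percentage and the
#' RIP-vs-bioimpedance breath-count agreement,
#' `breath_variation_percent = (breaths_rip - breaths_bioimpedance) /
#' breaths_rip * 100` (the RIP sensor is the reference).
#'
#' @param controlled,free_living named numeric vectors (or 1-row data
#'   frames) of event counts per portion. Recognized names:
#'   `lighter_press_release`, `cigarettes_from_lighter`,
#'   `cigarettes_self_report`, `h2m_from_imu`, `breaths_rip`,
#'   `breaths_bioimpedance`, `h2m_proximity`. Missing rows default to 0.
#' @param mask optional [usability_mask()]; supplies `usable_percent`.
#' @param hr optional `hr_summary` from [summarize_heart_rate()].
#' @return Object of class `summary_report`: `$counts` (data frame with
#'   columns `controlled`, `free_living`, `total`),
#'   `$breath_variation_percent`, `$usable_percent`, `$hr`.
#' @examples
#' summarize_study(c(lighter_press_release = 193),
#'                 c(lighter_press_release = 356))$counts
#' @export
summarize_study <- function(controlled, free_living, mask = NULL,
                            hr = NULL) {
  rows <- c("lighter_press_release", "cigarettes_from_lighter",
            "cigarettes_self_report", "h2m_from_imu", "breaths_rip",
            "breaths_bioimpedance", "h2m_proximity")
  as_counts <- function(x) {
    x <- unlist(x)
    bad <- setdiff(names(x), rows)
    if (length(bad)) stop("unknown count row(s): ",
                          paste(bad, collapse = ", "))
    out <- stats::setNames(numeric(length(rows)), rows)
    out[names(x)] <- x
    out
  }
  ctrl <- as_counts(controlled); free <- as_counts(free_living)
  counts <- data.frame(controlled = ctrl, free_living = free,
                       total = ctrl + free, row.names = rows)
  bv <- if (counts["breaths_rip", "total"] > 0)
    (counts["breaths_rip", "total"] -
       counts["breaths_bioimpedance", "total"]) /
      counts["breaths_rip", "total"] * 100
  else NA_real_
  structure(
    list(counts = counts,
         breath_variation_percent = bv,
         usable_percent = if (!is.null(mask)) usable_percent(mask)
                          else NA_real_,
         hr = hr),
    class = "summary_report")
}

#' @export
print.summary_report <- function(x, ...) {
  cat("<summary_report>\n")
  print(round(x$counts, 1))
  if (!is.na(x$breath_variation_percent))
    cat(sprintf("breath variation (RIP vs bioimpedance): %.2f%%\n",
                trunc(x$breath_variation_percent * 100) / 100))
  if (!is.na(x$usable_percent))
    cat(sprintf("usable data: %.1f%%\n", x$usable_percent))
  if (!is.null(x$hr)) { cat("heart rate:\n"); print(x$hr) }
  invisible(x)
}

#' Validation-study event counts
#'
#' Per-portion event totals recorded by the 40-subject, 943-h validation
#' study of the sensor suite, shipped as a plain-text input for
#' reproducing the summary bookkeeping.
#'
#' @return data frame with columns `event`, `controlled`, `free_living`.
#' @export
study_event_counts <- function() {
  utils::read.csv(system.file("extdata", "study_event_counts.csv",
                              package = "smokesense"),
                  stringsAsFactors = FALSE)
}

#' Maximum normalized cross-correlation between two series
#'
#' Removes each series' mean, then scans lags and reports the maximum of
#' the locally normalized cross-correlation
#' `sum(a'_t b'_{t+l}) / sqrt(sum_overlap a'^2 * sum_overlap b'^2)`,
#' so an exactly shifted copy scores 1.0 at its alignment lag. With
#' `max_lag = 0` this reduces to the zero-lag Pearson correlation.
#'
#' @param a,b numeric series at the same sampling rate.
#' @param max_lag largest |lag| scanned, in samples (default: half the
#'   shorter series).
#' @param min_overlap smallest overlap (samples) for a lag to qualify.
#' @return list with `coefficient` (in [-1, 1]) and `lag` (samples; b is
#'   shifted by `lag` relative to a).
#' @export
xcorr_coefficient <- function(a, b, max_lag = NULL,
                              min_overlap = max(2L, min(length(a),
                                                        length(b)) %/% 10L)) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    stop("undefined-coefficient error: zero-variance input")
  a <- a - mean(a); b <- b - mean(b)
  na <- length(a); nb <- length(b)
  if (is.null(max_lag)) max_lag <- min(na, nb) %/% 2L
  ca2 <- c(0, cumsum(a^2)); cb2 <- c(0, cumsum(b^2))
  best <- -Inf; best_lag <- 0L
  for (l in seq(-max_lag, max_lag)) {
    # overlap: a[i] against b[i + l]
    i0 <- max(1L, 1L - l); i1 <- min(na, nb - l)
    if (i1 - i0 + 1L < min_overlap) next
    ai <- i0:i1; bi <- ai + l
    num <- sum(a[ai] * b[bi])
    den <- sqrt((ca2[i1 + 1L] - ca2[i0]) *
                  (cb2[i1 + l + 1L] - cb2[i0 + l]))
    if (den == 0) next
    r <- num / den
    if (r > best) { best <- r; best_lag <- l }
  }
  if (!is.finite(best))
    stop("undefined-coefficient error: no lag with sufficient overlap")
  list(coefficient = best, lag = best_lag)
}

#' Great-circle distance and GPS displacement statistics
#'
#' `haversine_m()` is the great-circle distance on a sphere of radius
#' 6,371,000 m. `displacement_stats()` measures each recorded fix's distance
#' to the nearest vertex of the reference route and returns the mean and sd.
#'
#' @param lat1,lon1,lat2,lon2 coordinates in WGS-84 decimal degrees.
#' @return `haversine_m()`: distance(s) in meters.
#' @export
haversine_m <- function(lat1, lon1, lat2, lon2) {
  if (any(abs(c(lat1, lat2)) > 90) || any(abs(c(lon1, lon2)) > 180))
    stop("range error: |lat| <= 90 and |lon| <= 180 required")
  geosphere::distHaversine(cbind(lon1, lat1), cbind(lon2, lat2),
                           r = 6371000)
}

#' @rdname haversine_m
#' @param track data frame (or `sensor_stream`) of recorded fixes with
#'   latitude/longitude columns or channels.
#' @param route data frame of reference route vertices (`lat_deg`,
#'   `lon_deg`).
#' @return `displacement_stats()`: list with `mean_m` and `sd_m`.
#' @export
displacement_stats <- function(track, route) {
  if (inherits(track, "sensor_stream"))
    track <- data.frame(lat_deg = track$samples$latitude_deg,
                        lon_deg = track$samples$longitude_deg)
  d <- vapply(seq_len(nrow(track)), function(i)
    min(haversine_m(track$lat_deg[i], track$lon_deg[i],
                    route$lat_deg, route$lon_deg)), numeric(1))
  list(mean_m = mean(d), sd_m = stats::sd(d))
}

#' LC oscillator resonance physics
#'
#' `resonant_frequency_hz()` evaluates f0 = 1/(2 pi sqrt(L C));
#' `estimate_inductance()` inverts it, L = 1/((2 pi f0)^2 C). The belt
#' oscillator uses two 220-pF series capacitors, i.e. C = 110 pF.
#'
#' @param l_henries inductance (H), positive.
#' @param c_farads capacitance (F), positive.
#' @param f0_hz resonant frequency (Hz), positive.
#' @return frequency in Hz / inductance in henries.
#' @export
resonant_frequency_hz <- function(l_henries, c_farads) {
  if (any(l_henries <= 0) || any(c_farads <= 0))
    stop("domain error: L and C must be positive")
  1 / (2 * pi * sqrt(l_henries * c_farads))
}

#' @rdname resonant_frequency_hz
#' @export
estimate_inductance <- function(f0_hz, c_farads) {
  if (any(f0_hz <= 0) || any(c_farads <= 0))
    stop("domain error: f0 and C must be positive")
  1 / ((2 * pi * f0_hz)^2 * c_farads)
}

#' Convert a mean pulse count per window to MHz
#'
#' The counter logs oscillator pulses per `window_s` seconds; the implied
#' frequency `count / window_s` is reported truncated (not rounded) to two
#' decimals in MHz, matching the bench-report convention.
#'
#' @param mean_pulse_count mean pulses per window (> 0).
#' @param window_s counting window (default 10 ms).
#' @return frequency in MHz, truncated to 2 decimal places.
#' @examples
#' count_to_mhz(96199.76)  # 9.61
#' @export
count_to_mhz <- function(mean_pulse_count, window_s = 0.01) {
  if (any(mean_pulse_count <= 0)) stop("count must be positive")
  trunc(mean_pulse_count / window_s / 1e6 * 100) / 100
}

#' Coefficient of determination of the least-squares line
#'
#' R-squared of the ordinary least-squares fit `y ~ x`; used as the
#' linearity indicator of the belt's short-displacement response.
#'
#' @param x,y numeric vectors (>= 3 points; x not all equal).
#' @return R-squared in [0, 1].
#' @export
linearity_r2 <- function(x, y) {
  if (length(x) < 3L || length(x) != length(y))
    stop("need >= 3 paired points")
  if (stats::sd(x) == 0)
    stop("undefined error: degenerate x (all equal)")
  fit <- stats::lm(y ~ x)
  1 - sum(stats::residuals(fit)^2) / sum((y - mean(y))^2)
}
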