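# Linear clock-drift compensation: each device clock is initialized from the
# reference computer at t0 and read again alongside the computer clock at
# data extraction; a single correction factor f maps device time back to
# reference time.

#' Per-device clock model
#'
#' Linear model of a drifting device clock relative to the reference
#' (computer) clock: the device is set to the reference time `t0_s` at study
#' start and accumulates drift at a constant rate, so device time is
#' `t = t0 + f * (t_ref - t0)` with dimensionless correction factor `f`.
#'
#' @param device_id character scalar.
#' @param t0_s reference time at which the device clock was initialized (s).
#' @param f correction factor (> 0); 1 means no drift.
#' @param t_device_s,t_pc_s optional paired readout at extraction (device
#'   and computer clock); when given they must satisfy
#'   `f = (t_device_s - t0_s) / (t_pc_s - t0_s)`.
#' @return An object of class `clock_model`.
#' @export
clock_model <- function(device_id, t0_s, f, t_device_s = NULL,
                        t_pc_s = NULL) {
  if (!is.numeric(f) || length(f) != 1L || f <= 0)
    stop("correction factor f must be a positive scalar")
  if (!is.null(t_device_s) && !is.null(t_pc_s)) {
    f_imp <- (t_device_s - t0_s) / (t_pc_s - t0_s)
    if (abs(f_imp - f) > 1e-9 * max(1, abs(f)))
      stop("clock_model invariant violated: f does not match ",
           "(t_device - t0)/(t_pc - t0)")
  }
  structure(list(device_id = device_id, t0_s = as.numeric(t0_s),
                 f = as.numeric(f), t_device_s = t_device_s,
                 t_pc_s = t_pc_s),
            class = "clock_model")
}

#' @export
print.clock_model <- function(x, ...) {
  cat(sprintf("<clock_model> device '%s': t0 = %.3f s, f = %.12f (%+.3f s/day)\n",
              x$device_id, x$t0_s, x$f, (x$f - 1) * 86400))
  invisible(x)
}

#' Fit the clock correction factor from paired readouts
#'
#' `f` is the ratio `(t_device - t0) / (t_pc - t0)`, where both clocks are
#' read simultaneously at data extraction.
#'
#' @param t0_s reference time at device initialization (s).
#' @param t_device_s device clock at extraction (s).
#' @param t_pc_s computer clock at extraction (s); must exceed `t0_s`.
#' @param device_id device name for the resulting model.
#' @return A [clock_model()].
#' @examples
#' fit_clock(0, 86405, 86400)$f  # gained 5 s over a day
#' @export
fit_clock <- function(t0_s, t_device_s, t_pc_s, device_id = "device") {
  if (t_pc_s == t0_s)
    stop("degenerate-interval error: t_pc_s equals t0_s")
  if (t_pc_s < t0_s)
    stop("t_pc_s must be later than t0_s")
  clock_model(device_id, t0_s, f = (t_device_s - t0_s) / (t_pc_s - t0_s),
              t_device_s = t_device_s, t_pc_s = t_pc_s)
}

#' Compensate device timestamps onto the reference clock
#'
#' Applies the linear correction `t_c = (t - t0)/f + t0` elementwise.
#' Strictly monotone in its input, and the exact inverse of
#' [apply_clock_drift()].
#'
#' @param timestamps numeric vector of device-clock seconds.
#' @param clock a [clock_model()].
#' @return numeric vector of reference-clock seconds, order preserved.
#' @export
compensate <- function(timestamps, clock) {
  stopifnot(inherits(clock, "clock_model"))
  (timestamps - clock$t0_s) / clock$f + clock$t0_s
}

#' Compensate a whole stream or event log
#'
#' Event logs get both endpoints of every event corrected. Streams get a
#' corrected start time and sampling rate (`rate * f`), from which per-sample
#' timestamps are regenerated; the within-file rate error is absorbed by the
#' same linear factor.
#'
#' @param x a `sensor_stream` or `event_log` on the device clock.
#' @param clock a [clock_model()].
#' @return object of the same class on the reference clock.
#' @export
compensate_log <- function(x, clock) {
  stopifnot(inherits(x, "event_log"))
  x$events$t_start_s <- compensate(x$events$t_start_s, clock)
  x$events$t_end_s <- compensate(x$events$t_end_s, clock)
  x
}

#' @rdname compensate_log
#' @export
compensate_stream <- function(x, clock) {
  stopifnot(inherits(x, "sensor_stream"))
  x$start_time_s <- compensate(x$start_time_s, clock)
  x$rate_hz <- x$rate_hz * clock$f
  x
}
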