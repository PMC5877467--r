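# Per-sensor denoising chains. All filters are applied forward-backward
# (zero-phase), so event timestamps extracted downstream are not biased by
# filter group delay; outputs keep the input's length, rate and units.
#
# Every Butterworth stage here has order <= 2, i.e. a single biquad
# section - the numerically robust realization even for the extreme
# 0.001-Hz cutoff on 1-kHz data (checked at construction: the filter must
# actually null DC).

filter_channels <- function(stream, fun) {
  stream$samples <- lapply(stream$samples, fun)
  stream
}

butter_coefs <- function(cutoff_hz, order, rate_hz, type) {
  nyq <- rate_hz / 2
  if (any(cutoff_hz >= nyq))
    stop("parameter error: cutoff ", paste(cutoff_hz, collapse = "/"),
         " Hz not below the Nyquist frequency ", nyq, " Hz")
  if (any(cutoff_hz <= 0)) stop("parameter error: cutoff must be positive")
  bf <- signal::butter(order, cutoff_hz / nyq, type)
  if (type == "high") { # sanity: a high-pass must null DC exactly
    if (abs(sum(bf$b) / sum(bf$a)) > 1e-6)
      stop("filter design failed: high-pass does not null DC")
  }
  bf
}

#' Zero-phase Butterworth and smoothing filters for sensor streams
#'
#' Building blocks of the per-sensor conditioning chains. All are
#' length-preserving and zero-phase (forward-backward application), applied
#' independently to every channel.
#'
#' `smooth_gaussian()` implements the "average Gaussian filter of N points":
#' convolution with a normalized N-tap Gaussian kernel (sigma = N/6, so the
#' kernel is effectively supported on its taps), with edge replication.
#' `notch()` is a second-order Butterworth band-stop centred on `freq_hz`
#' with bandwidth `freq_hz / q` (default Q = 30, narrow enough to leave QRS
#' energy untouched).
#'
#' @param stream a [sensor_stream()].
#' @param cutoff_hz cutoff frequency in Hz (below Nyquist).
#' @param order filter order (1 or 2 in the standard chains).
#' @param freq_hz notch centre frequency in Hz.
#' @param q notch quality factor.
#' @param n_points Gaussian kernel length in samples (>= 1).
#' @return A `sensor_stream` of identical shape.
#' @export
highpass <- function(stream, cutoff_hz, order = 1) {
  bf <- butter_coefs(cutoff_hz, order, stream$rate_hz, "high")
  # demean first: the filter nulls DC anyway, and a large offset would
  # otherwise dominate the forward-backward edge transients
  filter_channels(stream, function(x)
    if (length(x) < 4L) x - mean(x) else
      as.numeric(signal::filtfilt(bf, x - mean(x))))
}

#' @rdname highpass
#' @export
lowpass <- function(stream, cutoff_hz, order = 2) {
  bf <- butter_coefs(cutoff_hz, order, stream$rate_hz, "low")
  filter_channels(stream, function(x)
    if (length(x) < 4L) x else as.numeric(signal::filtfilt(bf, x)))
}

#' @rdname highpass
#' @export
notch <- function(stream, freq_hz, q = 30) {
  bw <- freq_hz / q
  bf <- butter_coefs(c(freq_hz - bw / 2, freq_hz + bw / 2), 2,
                     stream$rate_hz, "stop")
  filter_channels(stream, function(x)
    if (length(x) < 8L) x else as.numeric(signal::filtfilt(bf, x)))
}

#' @rdname highpass
#' @export
smooth_gaussian <- function(stream, n_points) {
  if (n_points < 1L) stop("parameter error: n_points must be >= 1")
  n_points <- as.integer(n_points)
  if (n_points == 1L) return(stream)
  k <- seq_len(n_points) - (n_points + 1) / 2
  kern <- exp(-k^2 / (2 * (n_points / 6)^2))
  kern <- kern / sum(kern)
  p <- n_points
  offset <- (p - 1L) + (p %/% 2L)  # centers the kernel (+0.5 sample if even)
  filter_channels(stream, function(x) {
    n <- length(x)
    if (n == 0L) return(x)
    xp <- c(rep(x[1L], p - 1L), x, rep(x[n], p - 1L))
    yf <- stats::filter(xp, kern, method = "convolution", sides = 1L)
    as.numeric(yf[offset + seq_len(n)])
  })
}

#' The standard per-sensor conditioning chain
#'
#' Dispatches the denoising chain used before event detection:
#' \describe{
#'   \item{rip}{first-order high-pass at 0.1 Hz (motion artifacts), then a
#'     10-point Gaussian smoother.}
#'   \item{bioimpedance}{first-order high-pass at 0.001 Hz, then a 100-point
#'     Gaussian smoother.}
#'   \item{ecg}{first-order high-pass at 1 Hz, then a 60-Hz notch for
#'     power-line interference.}
#'   \item{imu}{second-order low-pass at 2 Hz.}
#'   \item{proximity}{50-point Gaussian smoother.}
#' }
#'
#' @param stream a [sensor_stream()].
#' @param sensor_kind one of `"rip"`, `"bioimpedance"`, `"ecg"`, `"imu"`,
#'   `"proximity"`.
#' @return conditioned `sensor_stream` (same length, rate, units).
#' @examples
#' tl <- simulate_behavior(sim_config(seed = 2, duration_s = 120,
#'                                    cigarettes_per_day = 0))
#' rip <- condition(render_rip(tl), "rip")
#' @export
condition <- function(stream, sensor_kind) {
  stopifnot(inherits(stream, "sensor_stream"))
  switch(sensor_kind,
    rip = smooth_gaussian(highpass(stream, 0.1, 1), 10),
    bioimpedance = smooth_gaussian(highpass(stream, 0.001, 1), 100),
    ecg = notch(highpass(stream, 1, 1), 60),
    imu = lowpass(stream, 2, 2),
    proximity = smooth_gaussian(stream, 50),
    stop("dispatch error: unknown sensor_kind '", sensor_kind, "'"))
}
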