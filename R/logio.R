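#' Multi-channel sensor stream
#'
#' In-memory representation of a uniformly sampled multi-channel recording on
#' a device-local clock. All downstream modules (conditioning, event
#' detection, summaries) consume this one container, whatever the sensor.
#'
#' @param device_id character scalar naming the recording device
#'   (e.g. `"chest_rip"`, `"hand_imu"`).
#' @param samples named list of equal-length numeric vectors, one per channel.
#' @param rate_hz sampling rate in Hz (> 0).
#' @param units character vector of per-channel unit strings (`"g"`, `"dps"`,
#'   `"mV"`, `"count"`, `"degrees"`, ...), recycled if length 1.
#' @param start_time_s device-clock time of the first sample, in seconds
#'   since the study epoch.
#' @return An object of class `sensor_stream`.
#' @examples
#' s <- sensor_stream("hand_imu",
#'                    list(ax = rnorm(100), ay = rnorm(100)),
#'                    rate_hz = 100, units = "g")
#' stream_times(s)[1:5]
#' @export
sensor_stream <- function(device_id, samples, rate_hz, units = "",
                          start_time_s = 0) {
  stopifnot(is.character(device_id), length(device_id) == 1L)
  if (!is.list(samples) || (length(samples) > 0L && is.null(names(samples))))
    stop("`samples` must be a named list of numeric vectors")
  lens <- vapply(samples, length, integer(1))
  if (length(lens) > 1L && length(unique(lens)) != 1L)
    stop("all channels must have the same length")
  if (!is.numeric(rate_hz) || length(rate_hz) != 1L || rate_hz <= 0)
    stop("`rate_hz` must be a positive scalar")
  units <- as.character(units)
  if (length(units) == 1L) units <- rep(units, length(samples))
  if (length(units) != length(samples))
    stop("`units` must have one entry per channel")
  structure(
    list(device_id = device_id,
         channels = names(samples),
         units = units,
         rate_hz = as.numeric(rate_hz),
         start_time_s = as.numeric(start_time_s),
         samples = lapply(samples, as.numeric)),
    class = "sensor_stream")
}

#' @rdname sensor_stream
#' @param stream a `sensor_stream`.
#' @export
stream_times <- function(stream) {
  n <- n_samples(stream)
  if (n == 0L) return(numeric(0))
  stream$start_time_s + (seq_len(n) - 1) / stream$rate_hz
}

#' @rdname sensor_stream
#' @export
n_samples <- function(stream) {
  if (length(stream$samples) == 0L) return(0L)
  length(stream$samples[[1L]])
}

#' @export
print.sensor_stream <- function(x, ...) {
  cat(sprintf("<sensor_stream> device '%s': %d channel(s) x %d samples @ %g Hz, start %.3f s\n",
              x$device_id, length(x$channels), n_samples(x), x$rate_hz,
              x$start_time_s))
  if (length(x$channels))
    cat("  channels:", paste0(x$channels, " [", x$units, "]", collapse = ", "),
        "\n")
  invisible(x)
}

#' Timestamped discrete event log
#'
#' Holds lighter press/release intervals, self-reported cigarettes, detected
#' breaths/R-peaks/proximity events and cigarette estimates. Events are kept
#' sorted by start time; zero-duration events (instantaneous detections) use
#' `t_end_s == t_start_s`.
#'
#' @param device_id character scalar.
#' @param kind character vector of event kinds; one of
#'   `"lighter_press"`, `"self_report_cigarette"`, `"detected_breath"`,
#'   `"detected_proximity"`, `"detected_rpeak"`, `"cigarette_estimate"`,
#'   `"pedometer_window"`.
#' @param t_start_s,t_end_s numeric vectors of event start/end times
#'   (seconds, `t_end_s >= t_start_s`).
#' @param attrs optional list (one named list per event) of extra key-value
#'   attributes, e.g. `list(step_count = 12)` for pedometer windows.
#' @return An object of class `event_log` with a data frame `$events`.
#' @export
event_log <- function(device_id, kind = character(), t_start_s = numeric(),
                      t_end_s = t_start_s, attrs = NULL) {
  kinds_ok <- c("lighter_press", "self_report_cigarette", "detected_breath",
                "detected_proximity", "detected_rpeak", "cigarette_estimate",
                "pedometer_window")
  kind <- as.character(kind)
  if (length(kind) && !all(kind %in% kinds_ok))
    stop("unknown event kind(s): ",
         paste(setdiff(unique(kind), kinds_ok), collapse = ", "))
  n <- length(kind)
  t_start_s <- as.numeric(t_start_s); t_end_s <- as.numeric(t_end_s)
  if (length(t_start_s) != n || length(t_end_s) != n)
    stop("kind, t_start_s and t_end_s must have equal length")
  if (any(t_end_s < t_start_s))
    stop("integrity error: t_end_s < t_start_s for event(s) ",
         paste(which(t_end_s < t_start_s), collapse = ", "))
  if (is.null(attrs)) attrs <- rep(list(list()), n)
  if (length(attrs) != n) stop("`attrs` must have one entry per event")
  o <- order(t_start_s, t_end_s)
  structure(
    list(device_id = device_id,
         events = data.frame(kind = kind[o], t_start_s = t_start_s[o],
                             t_end_s = t_end_s[o],
                             stringsAsFactors = FALSE),
         attrs = attrs[o]),
    class = "event_log")
}

#' @rdname event_log
#' @param log an `event_log`.
#' @export
n_events <- function(log) nrow(log$events)

#' @export
print.event_log <- function(x, ...) {
  cat(sprintf("<event_log> device '%s': %d event(s)\n", x$device_id,
              n_events(x)))
  if (n_events(x)) print(utils::head(x$events, 10L))
  invisible(x)
}

#' Usability mask over a recording
#'
#' Non-overlapping, sorted segments labelled `usable`, `removed` (device off
#' body / no valid signal) or `ambiguous` (sensors disagree), together
#' covering the full recording.
#'
#' @param t_start_s,t_end_s segment boundaries in seconds.
#' @param label per-segment label.
#' @return An object of class `usability_mask`.
#' @seealso [screen_usability()], [usable_percent()]
#' @export
usability_mask <- function(t_start_s, t_end_s, label) {
  stopifnot(length(t_start_s) == length(t_end_s),
            length(label) == length(t_start_s))
  label <- as.character(label)
  if (!all(label %in% c("usable", "removed", "ambiguous")))
    stop("labels must be usable/removed/ambiguous")
  o <- order(t_start_s)
  t_start_s <- as.numeric(t_start_s)[o]; t_end_s <- as.numeric(t_end_s)[o]
  label <- label[o]
  if (any(t_end_s <= t_start_s)) stop("segments must have positive duration")
  if (length(t_start_s) > 1L &&
      any(abs(t_start_s[-1L] - t_end_s[-length(t_end_s)]) > 1e-9))
    stop("segments must tile the recording without gaps or overlap")
  structure(
    data.frame(t_start_s = t_start_s, t_end_s = t_end_s, label = label,
               stringsAsFactors = FALSE),
    class = c("usability_mask", "data.frame"))
}

#' @rdname usability_mask
#' @param mask a `usability_mask`.
#' @return `usable_percent()`: percentage of the recording labelled usable.
#' @export
usable_percent <- function(mask) {
  dur <- mask$t_end_s - mask$t_start_s
  100 * sum(dur[mask$label == "usable"]) / sum(dur)
}

# -- on-disk formats ---------------------------------------------------------
# *.stream.csv : '#device,<id>' / '#rate_hz,<r>' / '#start_time_s,<t>' /
#                '#units,<u1>,<u2>,...' header block, then 't,<ch1>,<ch2>,...'
# *.events.csv : '#device,<id>' header, then 'kind,t_start,t_end,attrs_json'

#' Read and write sensor streams as delimited text
#'
#' The on-disk format is comma-separated UTF-8 text with a `#`-prefixed
#' header block carrying the device id, sampling rate, start time and
#' per-channel units, followed by a `t,<ch1>,<ch2>,...` table. Samples are
#' written with full double precision so that a write/read round trip is
#' lossless. Timestamps in the file are device-local seconds.
#'
#' @param path file path (conventionally `*.stream.csv`).
#' @param stream a [sensor_stream()].
#' @return `read_stream()` returns a `sensor_stream`; `write_stream()`
#'   returns `path` invisibly.
#' @export
read_stream <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, encoding = "UTF-8")
  hdr <- grep("^#", lines)
  if (length(hdr) < 3L || !identical(hdr, seq_along(hdr)))
    stop("format error: missing or broken header block in ", path)
  get_hdr <- function(key) {
    ln <- lines[hdr][startsWith(lines[hdr], paste0("#", key, ","))]
    if (length(ln) != 1L) stop("format error: header '", key, "' missing")
    strsplit(sub(paste0("^#", key, ","), "", ln), ",", fixed = TRUE)[[1L]]
  }
  device <- get_hdr("device")
  rate <- as.numeric(get_hdr("rate_hz"))
  start <- as.numeric(get_hdr("start_time_s"))
  units <- get_hdr("units")
  body <- lines[-hdr]
  if (length(body) == 0L) stop("format error: missing column header row")
  cols <- strsplit(body[[1L]], ",", fixed = TRUE)[[1L]]
  if (cols[1L] != "t") stop("format error: first column must be 't'")
  chans <- cols[-1L]
  if (length(units) == 1L && length(chans) > 1L)
    units <- rep(units, length(chans))
  dat <- if (length(body) > 1L) {
    d <- utils::read.csv(text = body[-1L], header = FALSE,
                         col.names = cols, colClasses = "character")
    d[] <- lapply(d, function(v) suppressWarnings(as.numeric(v)))
    d
  } else {
    as.data.frame(matrix(numeric(0), ncol = length(cols),
                         dimnames = list(NULL, cols)))
  }
  bad <- which(!stats::complete.cases(dat))
  if (length(bad))
    stop("format error: malformed row(s) ", paste(bad, collapse = ", "))
  if (nrow(dat) > 1L && any(diff(dat$t) <= 0))
    stop("integrity error: time column not strictly increasing (row ",
         which(diff(dat$t) <= 0)[1L] + 1L, ")")
  samples <- as.list(dat[chans])
  if (length(chans) == 0L) samples <- stats::setNames(list(), character(0))
  sensor_stream(device, samples, rate_hz = rate, units = units,
                start_time_s = if (nrow(dat)) dat$t[1L] else start)
}

#' @rdname read_stream
#' @export
write_stream <- function(stream, path) {
  stopifnot(inherits(stream, "sensor_stream"))
  con <- try(file(path, "w", encoding = "UTF-8"), silent = TRUE)
  if (inherits(con, "try-error")) stop("cannot write to ", path)
  on.exit(close(con))
  writeLines(c(paste0("#device,", stream$device_id),
               paste0("#rate_hz,", format(stream$rate_hz, digits = 17)),
               paste0("#start_time_s,",
                      format(stream$start_time_s, digits = 17)),
               paste0("#units,", paste(stream$units, collapse = ","))), con)
  writeLines(paste(c("t", stream$channels), collapse = ","), con)
  n <- n_samples(stream)
  if (n) {
    tt <- sprintf("%.17g", stream_times(stream))
    cols <- vapply(stream$samples, function(v) sprintf("%.17g", v),
                   character(n))
    if (n == 1L) cols <- matrix(cols, nrow = 1L)
    writeLines(do.call(paste, c(list(tt), asplit(cols, 2L), sep = ",")), con)
  }
  invisible(path)
}

#' Read and write event logs as delimited text
#'
#' Format: a `#device,<id>` header line, then a
#' `kind,t_start,t_end,attrs_json` CSV table. The `attrs_json` column holds a
#' JSON object per event (quoted, so embedded commas are safe); it survives a
#' round trip unchanged. Events are sorted by start time on read.
#'
#' @param path file path (conventionally `*.events.csv`).
#' @param log an [event_log()].
#' @return `read_event_log()` returns an `event_log`; `write_event_log()`
#'   returns `path` invisibly.
#' @export
read_event_log <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, encoding = "UTF-8")
  if (!length(lines) || !startsWith(lines[1L], "#device,"))
    stop("format error: missing '#device' header in ", path)
  device <- sub("^#device,", "", lines[1L])
  body <- lines[-1L]
  if (!length(body) || body[1L] != "kind,t_start,t_end,attrs_json")
    stop("format error: missing column header row")
  if (length(body) == 1L) return(event_log(device))
  dat <- utils::read.csv(text = body, header = TRUE,
                         colClasses = c("character", "numeric", "numeric",
                                        "character"))
  attrs <- lapply(dat$attrs_json, function(j)
    if (is.na(j) || !nzchar(j)) list()
    else jsonlite::fromJSON(j, simplifyVector = TRUE))
  event_log(device, kind = dat$kind, t_start_s = dat$t_start,
            t_end_s = dat$t_end, attrs = attrs)
}

#' @rdname read_event_log
#' @export
write_event_log <- function(log, path) {
  stopifnot(inherits(log, "event_log"))
  con <- try(file(path, "w", encoding = "UTF-8"), silent = TRUE)
  if (inherits(con, "try-error")) stop("cannot write to ", path)
  on.exit(close(con))
  writeLines(paste0("#device,", log$device_id), con)
  writeLines("kind,t_start,t_end,attrs_json", con)
  if (n_events(log)) {
    js <- vapply(log$attrs, function(a)
      as.character(jsonlite::toJSON(a, auto_unbox = TRUE, digits = NA)),
      character(1))
    js <- gsub("\"", "\"\"", js)  # CSV-quote embedded quotes
    writeLines(sprintf("%s,%.17g,%.17g,\"%s\"", log$events$kind,
                       log$events$t_start_s, log$events$t_end_s, js), con)
  }
  invisible(path)
}
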