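# Shared fixtures and independent oracles for the suite.

# self-report session log for every cigarette in a timeline
sessions_of <- function(timeline, device = "phone") {
  event_log(device,
            kind = rep("self_report_cigarette", length(timeline$cigarettes)),
            t_start_s = vapply(timeline$cigarettes, `[[`, numeric(1),
                               "t_light_s"),
            t_end_s = vapply(timeline$cigarettes, `[[`, numeric(1),
                             "t_end_s"))
}

# brute-force interval-matching oracle for lighter consolidation:
# plain nested loops, no shared code with consolidate_lighter()
oracle_consolidate <- function(press_times, sess_start, sess_end, merge_w) {
  assigned <- rep(NA_integer_, length(press_times))
  for (i in seq_along(press_times)) {
    for (j in seq_along(sess_start)) {
      if (press_times[i] >= sess_start[j] - merge_w &&
          press_times[i] <= sess_end[j]) { assigned[i] <- j; break }
    }
  }
  n_cig <- 0L
  for (j in seq_along(sess_start)) {
    pt <- sort(press_times[!is.na(assigned) & assigned == j])
    if (!length(pt)) next
    n_cig <- n_cig + 1L
    if (length(pt) > 1L)
      n_cig <- n_cig + sum(diff(pt) > merge_w)
  }
  list(n_cigarettes = n_cig, n_false = sum(is.na(assigned)))
}

# brute-force local maxima: x[i] is a peak if it is the strict maximum of
# its +/- w window (w in samples)
oracle_window_peaks <- function(x, w) {
  n <- length(x)
  out <- integer(0)
  for (i in 2:(n - 1)) {
    lo <- max(1, i - w); hi <- min(n, i + w)
    if (x[i] == max(x[lo:hi]) && x[i] > x[i - 1] && x[i] > x[i + 1] &&
        sum(x[lo:hi] == x[i]) == 1L)
      out <- c(out, i)
  }
  out
}

# O(n^2) lag-scan cross-correlation oracle, locally normalized, coded
# independently of xcorr_coefficient()
oracle_xcorr <- function(a, b, max_lag) {
  a <- a - mean(a); b <- b - mean(b)
  best <- -Inf; best_lag <- NA_integer_
  min_ov <- max(2, min(length(a), length(b)) %/% 10)
  for (l in -max_lag:max_lag) {
    num <- 0; da <- 0; db <- 0; n_ov <- 0
    for (i in seq_along(a)) {
      j <- i + l
      if (j >= 1 && j <= length(b)) {
        num <- num + a[i] * b[j]
        da <- da + a[i]^2; db <- db + b[j]^2
        n_ov <- n_ov + 1
      }
    }
    if (n_ov < min_ov || da == 0 || db == 0) next
    r <- num / sqrt(da * db)
    if (r > best) { best <- r; best_lag <- l }
  }
  list(coefficient = best, lag = best_lag)
}
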