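# Events-of-interest detection on band-limited signals. Both detectors share
# the run logic: an energy trace is thresholded at mean + n*SD (computed over
# the whole epoch), supra-threshold runs closer than merge_gap_s are merged,
# runs shorter than min_duration_s are dropped, and surviving runs must
# contain at least min_peaks rectified-signal peaks above their own
# mean + peak_threshold_sd * SD.

#' RMS detector parameters (Staba-style)
#'
#' Defaults follow the cited detector literature: 3 ms RMS window, 5 SD
#' threshold, 6 ms minimum duration, 6 rectified peaks above 3 SD, 10 ms
#' merge gap.
#'
#' @param window_s Sliding RMS window, seconds.
#' @param threshold_sd Threshold multiplier n (mean + n*SD of the RMS trace).
#' @param min_duration_s Minimum event duration, seconds.
#' @param min_peaks Minimum number of rectified peaks in an event.
#' @param peak_threshold_sd Multiplier for the rectified-peak threshold.
#' @param merge_gap_s Runs closer than this are merged before the duration
#'   test.
#' @return An `rms_params` list.
#' @export
rms_params <- function(window_s = 0.003, threshold_sd = 5,
                       min_duration_s = 0.006, min_peaks = 6L,
                       peak_threshold_sd = 3, merge_gap_s = 0.010) {
  stopifnot(window_s > 0, threshold_sd > 0, min_duration_s > 0,
            min_peaks >= 1L, peak_threshold_sd > 0, merge_gap_s > 0)
  structure(list(window_s = window_s, threshold_sd = threshold_sd,
                 min_duration_s = min_duration_s, min_peaks = as.integer(min_peaks),
                 peak_threshold_sd = peak_threshold_sd, merge_gap_s = merge_gap_s),
            class = "rms_params")
}

#' Hilbert-envelope detector parameters (Burnos-style)
#'
#' @param threshold_sd Threshold multiplier for the envelope.
#' @param min_duration_s Minimum event duration, seconds (default 10 ms).
#' @param min_peaks Minimum number of rectified peaks in an event.
#' @param peak_threshold_sd Multiplier for the rectified-peak threshold.
#' @param merge_gap_s Merge gap, seconds.
#' @return A `hilbert_params` list.
#' @export
hilbert_params <- function(threshold_sd = 3, min_duration_s = 0.010,
                           min_peaks = 6L, peak_threshold_sd = 3,
                           merge_gap_s = 0.010) {
  stopifnot(threshold_sd > 0, min_duration_s > 0, min_peaks >= 1L,
            peak_threshold_sd > 0, merge_gap_s > 0)
  structure(list(threshold_sd = threshold_sd, min_duration_s = min_duration_s,
                 min_peaks = as.integer(min_peaks),
                 peak_threshold_sd = peak_threshold_sd,
                 merge_gap_s = merge_gap_s),
            class = "hilbert_params")
}

#' Centered sliding-window RMS
#'
#' Same length as the input; edge windows are truncated.
#'
#' @param x Numeric signal.
#' @param rate Samples/s.
#' @param window_s Window length in seconds (>= 1 sample, <= signal length).
#' @return Numeric RMS trace.
#' @export
sliding_rms <- function(x, rate, window_s) {
  n <- length(x)
  w <- max(1L, as.integer(round(window_s * rate)))
  if (w > n) stop("sliding_rms(): window (", w, " samples) longer than signal")
  half_l <- (w - 1L) %/% 2L
  half_r <- w - 1L - half_l
  cs <- cumsum(c(0, x^2))
  i <- seq_len(n)
  lo <- pmax(i - half_l, 1L)
  hi <- pmin(i + half_r, n)
  sqrt((cs[hi + 1L] - cs[lo]) / (hi - lo + 1L))
}

#' Hilbert envelope (magnitude of the analytic signal)
#'
#' @param x Numeric signal.
#' @return Envelope, same length as `x`.
#' @export
hilbert_envelope <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1; h[2:((n + 1) / 2)] <- 2
  }
  Mod(stats::fft(X * h, inverse = TRUE) / n)
}

# supra-threshold run extraction + merge + duration + peak-count filtering;
# returns a two-column matrix of 1-based [start, end] sample indices
threshold_runs <- function(energy, x, rate, threshold, min_duration_s,
                           merge_gap_s, min_peaks, peak_threshold_sd) {
  above <- energy > threshold
  if (!any(above)) return(matrix(integer(), ncol = 2L))
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- cbind(starts[r$values], ends[r$values])
  # merge runs separated by less than merge_gap_s (merge, then duration test)
  gap <- as.integer(round(merge_gap_s * rate))
  merged <- runs[1, , drop = FALSE]
  for (i in seq_len(nrow(runs) - 1L) + 1L) {
    if (runs[i, 1L] - merged[nrow(merged), 2L] - 1L < gap) {
      merged[nrow(merged), 2L] <- runs[i, 2L]
    } else {
      merged <- rbind(merged, runs[i, , drop = FALSE])
    }
  }
  min_len <- max(1L, as.integer(round(min_duration_s * rate)))
  merged <- merged[merged[, 2L] - merged[, 1L] + 1L >= min_len, , drop = FALSE]
  if (!nrow(merged)) return(merged)
  # rectified-peak requirement over the whole-epoch rectified statistics
  rx <- abs(x)
  peak_thr <- mean(rx) + peak_threshold_sd * stats::sd(rx)
  peaks <- which(diff(sign(diff(rx))) < 0) + 1L      # strict local maxima
  peaks <- peaks[rx[peaks] > peak_thr]
  keep <- vapply(seq_len(nrow(merged)), function(i) {
    sum(peaks >= merged[i, 1L] & peaks <= merged[i, 2L]) >= min_peaks
  }, logical(1))
  merged[keep, , drop = FALSE]
}

detect_energy <- function(rec, energy_fn, rate_check, params) {
  out <- list()
  for (ei in seq_len(n_epochs(rec))) {
    ep <- rec$epochs[[ei]]
    for (ch in ep) {
      x <- ch$samples
      if (stats::sd(x) == 0) next                    # zero-variance guard
      energy <- energy_fn(x, ch$rate)
      thr <- mean(energy) + params$threshold_sd * stats::sd(energy)
      runs <- threshold_runs(energy, x, ch$rate, thr, params$min_duration_s,
                             params$merge_gap_s, params$min_peaks,
                             params$peak_threshold_sd)
      if (!nrow(runs)) next
      out[[length(out) + 1L]] <- event_list(
        epoch_index = rep(ei, nrow(runs)),
        channel = rep(ch$name, nrow(runs)),
        onset = (runs[, 1L] - 1L) / ch$rate,
        duration = (runs[, 2L] - runs[, 1L] + 1L) / ch$rate,
        label = rep("EOI", nrow(runs)))
    }
  }
  if (!length(out)) return(event_list())
  do.call(bind_events, out)
}

#' RMS (Staba-style) events-of-interest detector
#'
#' The input is expected to be band-pass filtered already (the detector
#' does not filter). Events where the sliding RMS exceeds
#' `mean + threshold_sd * SD` are extracted with the shared run logic and
#' labeled `EOI`.
#'
#' @param rec A band-limited `hfo_recording`.
#' @param params An [rms_params()] set.
#' @return An `hfo_events` list of `EOI` markers.
#' @export
detect_rms <- function(rec, params = rms_params()) {
  detect_energy(rec, function(x, rate) sliding_rms(x, rate, params$window_s),
                TRUE, params)
}

#' Hilbert-envelope (Burnos-style) events-of-interest detector
#'
#' @param rec A band-limited `hfo_recording`.
#' @param params A [hilbert_params()] set.
#' @return An `hfo_events` list of `EOI` markers.
#' @export
detect_hilbert <- function(rec, params = hilbert_params()) {
  detect_energy(rec, function(x, rate) hilbert_envelope(x), TRUE, params)
}
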