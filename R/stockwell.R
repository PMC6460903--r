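# Stockwell (S-) transform and the spectral peak/trough classification rule:
# an event is a genuine HFO when the instantaneous spectrum around its
# amplitude maximum shows a high-frequency peak that is isolated from the
# low-frequency activity by a trough, with a peak/trough magnitude ratio of
# at least theta; the ripple/fast-ripple boundary is 250 Hz.

#' Stockwell transform (FFT formulation)
#'
#' Computes the S-transform magnitude for the DFT frequency rows whose
#' frequency lies in `[f_lo, f_hi]` Hz (row f = 0 excluded), using the
#' frequency-domain formulation: row n is the inverse FFT of the shifted
#' spectrum windowed by the Gaussian `exp(-2 pi^2 m^2 / n^2)`.
#'
#' @param x Numeric segment, length >= 16.
#' @param rate Samples/s.
#' @param f_lo,f_hi Frequency band, `f_hi <= rate/2`.
#' @return A frequencies x time magnitude matrix; row names give the row
#'   frequencies in Hz.
#' @export
stockwell_transform <- function(x, rate, f_lo = 1, f_hi = 500) {
  n <- length(x)
  if (n < 16L) stop("stockwell_transform(): segment too short (", n, " < 16)")
  if (f_hi > rate / 2 + 1e-9) stop("stockwell_transform(): f_hi above Nyquist")
  H <- stats::fft(x) / n
  rows <- which((seq_len(n) - 1) * rate / n >= f_lo &
                  (seq_len(n) - 1) * rate / n <= f_hi)
  rows <- rows[rows > 1L]                       # exclude f = 0
  m_signed <- c(0:(n %/% 2), -((n - n %/% 2 - 1L):1L))  # FFT bin order
  out <- matrix(0, length(rows), n)
  for (r in seq_along(rows)) {
    nn <- rows[r] - 1L                          # frequency index
    shifted <- H[((seq_len(n) - 1L + nn) %% n) + 1L]
    gauss <- exp(-2 * pi^2 * m_signed^2 / nn^2)
    out[r, ] <- Mod(stats::fft(shifted * gauss, inverse = TRUE))
  }
  rownames(out) <- format((rows - 1) * rate / n, trim = TRUE)
  out
}

#' Stockwell classifier parameters
#'
#' @param f_min,f_max High-frequency peak search band, Hz.
#' @param ripple_boundary Ripple / fast-ripple boundary, Hz.
#' @param peak_trough_ratio Threshold theta (>= 1) on HF-peak / trough
#'   magnitude.
#' @param context_s Symmetric context around the EOI included in the
#'   transform, seconds.
#' @param avg_window_s Averaging window around the amplitude maximum for
#'   the instantaneous spectrum, seconds.
#' @param smooth_hz Half-width of the boxcar applied to the profile before
#'   the extrema scan (suppresses 1 Hz-lattice noise wiggles).
#' @param floor_frac A low-frequency peak must exceed this fraction of the
#'   HF peak to count as structure; values at the numerical/stop-band
#'   floor (for example below a band-pass filter's cutoff) are not peaks.
#' @return A `stockwell_params` list.
#' @export
stockwell_params <- function(f_min = 60, f_max = 500, ripple_boundary = 250,
                             peak_trough_ratio = 2.0, context_s = 0.1,
                             avg_window_s = 0.010, smooth_hz = 3,
                             floor_frac = 1e-3) {
  stopifnot(f_min < ripple_boundary, ripple_boundary < f_max,
            peak_trough_ratio >= 1)
  structure(list(f_min = f_min, f_max = f_max,
                 ripple_boundary = ripple_boundary,
                 peak_trough_ratio = peak_trough_ratio,
                 context_s = context_s, avg_window_s = avg_window_s,
                 smooth_hz = smooth_hz, floor_frac = floor_frac),
            class = "stockwell_params")
}

#' Classify one event of interest with the S-transform rule
#'
#' The EOI plus symmetric context is zero-padded to at least one second of
#' effective length (1 Hz rows), S-transformed, and the column profile is
#' averaged over `avg_window_s` around the time of maximum absolute
#' amplitude inside the EOI. In the profile, the high-frequency peak is the
#' largest local maximum within `[f_min, f_max]`; scanning downward from
#' it, the first local minimum is the trough and the first local maximum
#' below the trough is the low-frequency peak. The event is an HFO when
#' `profile[HF] / profile[trough] >= peak_trough_ratio` and the trough lies
#' strictly between the two peaks: label `R` below `ripple_boundary`,
#' else `F`. Anything else is an artifact, `A`.
#'
#' @param eoi One-row `hfo_events`.
#' @param rec The `hfo_recording` to classify against.
#' @param params A [stockwell_params()].
#' @return A list with `label` (`"R"`, `"F"`, `"A"`), `peak_freq`,
#'   `ratio`, and `reason` (set when labeled `A`).
#' @export
classify_eoi_stockwell <- function(eoi, rec, params = stockwell_params()) {
  ch <- get_channel(rec, eoi$channel, eoi$epoch_index)
  rate <- ch$rate
  dur <- epoch_duration(rec$epochs[[eoi$epoch_index]])
  t0 <- max(0, eoi$onset - params$context_s)
  t1 <- min(dur, eoi$onset + eoi$duration + params$context_s)
  i0 <- sec_to_idx(t0, rate)
  i1 <- sec_to_idx(t1, rate)
  seg <- ch$samples[(i0 + 1L):i1]
  n_seg <- length(seg)
  # zero-pad to >= 1 s effective length so rows land on a <= 1 Hz lattice
  n_pad <- max(n_seg, as.integer(ceiling(rate)))
  segp <- c(seg, numeric(n_pad - n_seg))

  f_floor <- max(1, params$f_min / 6)           # profile extends below f_min
  st <- stockwell_transform(segp, rate, f_floor, params$f_max)
  freqs <- as.numeric(rownames(st))

  # time of maximum |amplitude| within the EOI proper
  e0 <- sec_to_idx(eoi$onset, rate) - i0
  e1 <- sec_to_idx(eoi$onset + eoi$duration, rate) - i0
  e0 <- max(e0, 0L); e1 <- min(e1, n_seg)
  t_max <- e0 + which.max(abs(seg[(e0 + 1L):e1]))
  half_w <- max(1L, as.integer(round(params$avg_window_s / 2 * rate)))
  cols <- max(1L, t_max - half_w):min(n_seg, t_max + half_w)
  profile <- rowMeans(st[, cols, drop = FALSE])
  # boxcar smoothing over +/- smooth_hz rows before the extrema scan
  bw <- 2L * as.integer(round(params$smooth_hz / max(diff(freqs)[1], 1e-9))) + 1L
  if (bw > 1L && length(profile) > bw) {
    sm <- stats::filter(profile, rep(1 / bw, bw), sides = 2)
    profile <- ifelse(is.na(sm), profile, as.numeric(sm))
  }

  res <- function(label, peak = NA_real_, ratio = NA_real_, reason = NA_character_) {
    list(label = label, peak_freq = peak, ratio = ratio, reason = reason)
  }
  np <- length(profile)
  is_lmax <- c(FALSE, diff(sign(diff(profile))) < 0, FALSE)
  is_lmin <- c(FALSE, diff(sign(diff(profile))) > 0, FALSE)
  # endpoints may serve as extrema for the downward scan
  is_lmax[1] <- profile[1] > profile[2]
  is_lmin[1] <- profile[1] < profile[2]

  in_band <- freqs >= params$f_min & freqs <= params$f_max
  cand <- which(is_lmax & in_band)
  if (!length(cand)) {
    return(res("A", reason = "no local maximum in the HF search band"))
  }
  hf <- cand[which.max(profile[cand])]
  trough <- NA_integer_
  for (i in rev(seq_len(hf - 1L))) {
    if (is_lmin[i]) { trough <- i; break }
  }
  if (is.na(trough)) {
    return(res("A", freqs[hf], reason = "no trough below the HF peak"))
  }
  lf <- NA_integer_
  floor_mag <- params$floor_frac * profile[hf]
  for (i in rev(seq_len(trough - 1L))) {
    if (is_lmax[i] && profile[i] > floor_mag) { lf <- i; break }
  }
  if (is.na(lf)) {
    return(res("A", freqs[hf], reason = "no low-frequency peak below the trough"))
  }
  ratio <- profile[hf] / max(profile[trough], .Machine$double.xmin)
  if (ratio < params$peak_trough_ratio) {
    return(res("A", freqs[hf], ratio, "peak/trough ratio below threshold"))
  }
  label <- if (freqs[hf] < params$ripple_boundary) "R" else "F"
  res(label, freqs[hf], ratio)
}

#' Classify every event of an event list with the S-transform rule
#'
#' @param events An `hfo_events` list (typically detector output).
#' @param rec The `hfo_recording`.
#' @param params A [stockwell_params()].
#' @return The event list with labels rewritten and `peak_freq` /
#'   `st_ratio` property columns.
#' @export
classify_events_stockwell <- function(events, rec, params = stockwell_params()) {
  if (!nrow(events)) return(events)
  labels <- character(nrow(events))
  peaks <- numeric(nrow(events))
  ratios <- numeric(nrow(events))
  for (i in seq_len(nrow(events))) {
    r <- classify_eoi_stockwell(events[i, ], rec, params)
    labels[i] <- r$label
    peaks[i] <- r$peak_freq
    ratios[i] <- r$ratio
  }
  events$label <- labels
  events$peak_freq <- peaks
  events$st_ratio <- ratios
  as_event_list(events)
}
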