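# Windowed-sinc FIR filtering. Kernels are Blackman-windowed sinc functions;
# a band-pass is the composition (time-domain convolution) of a high-pass at
# the lower edge with a low-pass at the upper edge. Optional self-convolution
# squares the frequency response, roughly doubling stop-band attenuation in
# dB (below -145 dB for the defaults).

blackman_window <- function(n) {
  k <- seq_len(n) - 1
  0.42 - 0.5 * cos(2 * pi * k / (n - 1)) + 0.08 * cos(4 * pi * k / (n - 1))
}

sinc_lowpass <- function(fc_norm, taps) {
  m <- taps - 1L
  k <- seq_len(taps) - 1L - m / 2
  h <- ifelse(k == 0, 2 * fc_norm, sin(2 * pi * fc_norm * k) / (pi * k))
  h <- h * blackman_window(taps)
  h / sum(h)                                  # unit DC gain
}

#' Design a Blackman-windowed sinc FIR kernel
#'
#' Low-pass (`high_hz` only), high-pass (`low_hz` only; spectral inversion
#' of the low-pass) or band-pass (both; high-pass composed with low-pass).
#' With `self_convolve = TRUE` the finished kernel is convolved with itself,
#' squaring its frequency response.
#'
#' @param low_hz,high_hz Optional cutoffs in Hz, `0 < cutoff < rate/2`;
#'   at least one must be given, and `low_hz < high_hz` for a band-pass.
#' @param rate Sampling rate the kernel is designed for, samples/s.
#' @param taps Base kernel length; odd, >= 31. Default 513 (~256 ms at
#'   2 kHz), long enough to reach the quoted stop-band floor with a
#'   practical transition width.
#' @param self_convolve Convolve the kernel with itself.
#' @return A `fir_kernel`: coefficients `taps`, the design parameters, and
#'   `base_taps` (used for the transition-width estimate
#'   `tw = 4 * rate / base_taps`).
#' @export
design_fir <- function(low_hz = NULL, high_hz = NULL, rate, taps = 513L,
                       self_convolve = FALSE) {
  if (is.null(low_hz) && is.null(high_hz)) {
    stop("design_fir(): at least one cutoff must be given")
  }
  taps <- as.integer(taps)
  if (taps < 31L || taps %% 2L == 0L) stop("design_fir(): taps must be odd and >= 31")
  for (f in c(low_hz, high_hz)) {
    if (f <= 0 || f >= rate / 2) {
      stop("design_fir(): cutoff ", f, " Hz outside (0, ", rate / 2, ")")
    }
  }
  if (!is.null(low_hz) && !is.null(high_hz) && low_hz >= high_hz) {
    stop("design_fir(): low_hz must be < high_hz")
  }
  h <- NULL
  if (!is.null(low_hz)) {                      # high-pass at low edge
    lp <- sinc_lowpass(low_hz / rate, taps)
    hp <- -lp
    hp[(taps + 1L) %/% 2L] <- hp[(taps + 1L) %/% 2L] + 1
    h <- hp
  }
  if (!is.null(high_hz)) {                     # low-pass at high edge
    lp <- sinc_lowpass(high_hz / rate, taps)
    h <- if (is.null(h)) lp else conv_full(h, lp)
  }
  if (self_convolve) h <- conv_full(h, h)
  structure(list(taps = h, low_hz = low_hz, high_hz = high_hz, rate = rate,
                 base_taps = taps, self_convolved = self_convolve),
            class = "fir_kernel")
}

# full linear convolution via FFT, length(a) + length(b) - 1
conv_full <- function(a, b) {
  n <- length(a) + length(b) - 1L
  nf <- stats::nextn(n, c(2, 3, 5))
  y <- Re(stats::fft(stats::fft(c(a, numeric(nf - length(a)))) *
                       stats::fft(c(b, numeric(nf - length(b)))),
                     inverse = TRUE)) / nf
  y[seq_len(n)]
}

#' Frequency response of a FIR kernel
#'
#' @param kernel A `fir_kernel` (or bare coefficient vector with `rate`).
#' @param n_fft Zero-padded FFT length.
#' @param rate Sampling rate when `kernel` is a bare vector.
#' @return Data frame with `freq_hz` and `mag_db` over `[0, rate/2]`.
#' @export
fir_response <- function(kernel, n_fft = 2^17, rate = NULL) {
  if (inherits(kernel, "fir_kernel")) {
    h <- kernel$taps; rate <- kernel$rate
  } else h <- kernel
  H <- stats::fft(c(h, numeric(n_fft - length(h))))
  half <- seq_len(n_fft %/% 2 + 1L)
  data.frame(freq_hz = (half - 1) * rate / n_fft,
             mag_db = 20 * log10(pmax(Mod(H[half]), 1e-300)))
}

#' Maximum stop-band magnitude of a kernel, in dB
#'
#' The stop band is everything farther than the transition width
#' `tw = 4 * rate / base_taps` outside the pass band.
#'
#' @param kernel A `fir_kernel`.
#' @param n_fft FFT length for the response.
#' @return Maximum stop-band magnitude in dB (a negative number).
#' @export
fir_stopband_db <- function(kernel, n_fft = 2^17) {
  resp <- fir_response(kernel, n_fft)
  tw <- 4 * kernel$rate / kernel$base_taps
  lo <- kernel$low_hz %||% 0
  hi <- kernel$high_hz %||% (kernel$rate / 2)
  stop_sel <- (resp$freq_hz < lo - tw) | (resp$freq_hz > hi + tw)
  if (is.null(kernel$low_hz)) stop_sel <- resp$freq_hz > hi + tw
  if (is.null(kernel$high_hz)) stop_sel <- resp$freq_hz < lo - tw
  max(resp$mag_db[stop_sel])
}

#' Apply a FIR kernel to a recording
#'
#' Linear convolution via FFT with zero-padded edges; the group delay
#' `(length - 1) / 2` is compensated so the output is time-aligned with the
#' input and has the same length.
#'
#' @param rec An `hfo_recording` (every channel must match the kernel rate).
#' @param kernel A `fir_kernel`.
#' @return A filtered `hfo_recording`.
#' @export
apply_fir <- function(rec, kernel) {
  map_channels(rec, function(x, rate, name) {
    if (abs(rate - kernel$rate) > 1e-9) {
      stop("apply_fir(): channel '", name, "' rate ", rate,
           " != kernel rate ", kernel$rate)
    }
    fir_filter_signal(x, kernel$taps)
  })
}

#' Filter a bare signal with FIR coefficients (FFT convolution,
#' delay-compensated)
#' @param x Numeric signal.
#' @param h Coefficient vector (odd length for exact alignment).
#' @return Filtered signal, same length as `x`.
#' @export
fir_filter_signal <- function(x, h) {
  y <- conv_full(x, h)
  d <- (length(h) - 1L) %/% 2L
  y[(d + 1L):(d + length(x))]
}
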