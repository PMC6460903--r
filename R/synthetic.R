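# Synthetic EEG with exact ground truth: 1/f ("pink") background plus
# injected tapered HFO bursts and sharp biphasic spike transients. The spike
# exists to exercise the "false ripple" failure mode: band-pass filtering a
# broadband transient rings at the filter's center frequency and mimics an
# oscillation.

with_seed <- function(seed, code) {
  if (!is.null(old <- globalenv()$.Random.seed)) {
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(if (exists(".Random.seed", globalenv()))
      rm(".Random.seed", envir = globalenv()))
  }
  set.seed(as.integer(seed))   # R's default generator is Mersenne-Twister
  force(code)
}

#' Simulation configuration
#'
#' @param n_channels Number of channels.
#' @param duration_s Recording duration, seconds.
#' @param rate Sampling rate, samples/s; must satisfy Nyquist for every
#'   configured injection frequency.
#' @param background_scale Standard deviation of the background, microvolt.
#' @param pink_exponent Target spectral exponent (power ~ 1/f^a); default 1.
#' @param seed Mandatory integer seed; all outputs are pure functions of
#'   (config, seed).
#' @param events Optional stochastic event configuration from
#'   [sim_events_config()].
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_channels = 1L, duration_s = 10, rate = 2000,
                       background_scale = 25, pink_exponent = 1,
                       seed, events = NULL) {
  if (missing(seed)) stop("sim_config(): seed is mandatory")
  cfg <- list(n_channels = as.integer(n_channels), duration_s = duration_s,
              rate = rate, background_scale = background_scale,
              pink_exponent = pink_exponent, seed = as.integer(seed),
              events = events)
  if (!is.null(events)) {
    fmax <- events$f_max %||% 500
    if (rate < 2 * fmax) {
      stop("sim_config(): rate ", rate, " violates Nyquist for events up to ",
           fmax, " Hz")
    }
  }
  structure(cfg, class = "sim_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Stochastic event-population configuration
#'
#' Per-recording counts for each class; injection parameters are drawn
#' uniformly from the stated ranges. Amplitudes are expressed as a multiple
#' (`snr`) of the in-band standard deviation of the background in the
#' event's own band.
#'
#' @param n_ripple,n_fast,n_spike Events per recording per class.
#' @param snr Amplitude in units of in-band background SD (default 5).
#' @param ripple_f Frequency range for ripples (Hz).
#' @param fast_f Frequency range for fast ripples (Hz).
#' @param cycles Range of whole cycles per HFO burst.
#' @param min_gap_s Minimum gap between consecutive event onsets, seconds.
#' @return A list used by [generate_labeled_dataset()].
#' @export
sim_events_config <- function(n_ripple = 10L, n_fast = 5L, n_spike = 5L,
                              snr = 5, ripple_f = c(90, 240),
                              fast_f = c(260, 450), cycles = c(8L, 16L),
                              min_gap_s = 0.3) {
  list(n_ripple = n_ripple, n_fast = n_fast, n_spike = n_spike, snr = snr,
       ripple_f = ripple_f, fast_f = fast_f, cycles = cycles,
       min_gap_s = min_gap_s, f_max = max(fast_f))
}

pink_noise <- function(n, exponent = 1) {
  w <- stats::rnorm(n)
  X <- stats::fft(w)
  f <- c(1, seq_len(n - 1))            # bin index; DC reuses bin 1 weight
  f <- pmin(f, n - f + 1)              # fold to two-sided frequency distance
  amp <- 1 / f^(exponent / 2)
  amp[1] <- 0                          # remove DC
  x <- Re(stats::fft(X * amp, inverse = TRUE)) / n
  x
}

#' Generate 1/f background EEG
#'
#' Per channel: spectrally shaped Gaussian noise with power spectral density
#' proportional to 1/f^`pink_exponent`, rescaled to `background_scale`
#' standard deviation. Bitwise reproducible for a fixed config.
#'
#' @param config A [sim_config()].
#' @return An `hfo_recording` with one epoch.
#' @export
generate_background <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- as.integer(round(config$duration_s * config$rate))
  with_seed(config$seed, {
    chans <- lapply(seq_len(config$n_channels), function(k) {
      x <- pink_noise(n, config$pink_exponent)
      x <- x / stats::sd(x) * config$background_scale
      channel(sprintf("CH%02d", k), config$rate, x)
    })
    recording(epoch(chans), subject_id = sprintf("sim-seed-%d", config$seed))
  })
}

#' In-band standard deviation of a signal
#'
#' SD of the ideally band-limited component, computed from the periodogram
#' (sum of spectral power over `[lo, hi]` Hz). Used to calibrate injection
#' amplitudes in SNR units.
#'
#' @param x Numeric signal.
#' @param rate Samples/s.
#' @param lo,hi Band edges in Hz.
#' @return The in-band SD, same units as `x`.
#' @export
band_sd <- function(x, rate, lo, hi) {
  n <- length(x)
  X <- stats::fft(x - mean(x))
  f <- (seq_len(n) - 1) * rate / n
  f <- pmin(f, rate - f)               # two-sided -> absolute frequency
  sel <- f >= lo & f <= hi
  sqrt(sum(Mod(X[sel])^2) / n^2)
}

#' Injection specification
#'
#' @param channel Target channel name.
#' @param t0 Burst onset, seconds from epoch start.
#' @param f0 Oscillation frequency, Hz (HFO kind: 80-500).
#' @param n_cycles Whole cycles (>= 3); burst duration is `n_cycles / f0`.
#' @param amplitude Peak amplitude, microvolt.
#' @param taper Fraction (0-0.5) of the burst Hann-ramped at each end.
#' @param kind `"hfo"` or `"spike"` (`f0`/`n_cycles` ignored for spikes).
#' @return An `injection_spec` list.
#' @export
injection_spec <- function(channel, t0, f0 = 140, n_cycles = 12L,
                           amplitude = 50, taper = 0.25, kind = "hfo") {
  kind <- match.arg(kind, c("hfo", "spike"))
  if (kind == "hfo") {
    if (f0 < 80 || f0 > 500) stop("injection_spec(): HFO f0 must be in [80, 500] Hz")
    if (n_cycles < 3L) stop("injection_spec(): n_cycles must be >= 3")
  }
  stopifnot(taper >= 0, taper <= 0.5)
  structure(list(channel = channel, t0 = t0, f0 = f0,
                 n_cycles = as.integer(n_cycles), amplitude = amplitude,
                 taper = taper, kind = kind),
            class = "injection_spec")
}

spike_width_s <- 0.005  # biphasic transient base width

hfo_burst_wave <- function(spec, rate) {
  dur <- spec$n_cycles / spec$f0
  n <- max(1L, as.integer(round(dur * rate)))
  t <- (seq_len(n) - 1) / rate
  w <- spec$amplitude * sin(2 * pi * spec$f0 * t)
  nt <- as.integer(floor(spec$taper * n))
  if (nt > 0L) {
    ramp <- 0.5 * (1 - cos(pi * (seq_len(nt) - 0.5) / nt))  # Hann on/off
    w[seq_len(nt)] <- w[seq_len(nt)] * ramp
    w[(n - nt + 1L):n] <- w[(n - nt + 1L):n] * rev(ramp)
  }
  w
}

spike_wave <- function(spec, rate) {
  # difference of two Gaussians: a sharp positive deflection (~5 ms base
  # width) minus a shallower, wider undershoot. The weights keep the net
  # low-frequency content positive so the spectrum decays monotonically
  # from low frequencies, as for a real sharp transient; a near-zero-mean
  # wavelet would itself be a band-limited oscillation and could not
  # exercise the false-ripple failure mode.
  n <- max(3L, as.integer(round(3 * spike_width_s * rate)))
  t <- (seq_len(n) - 1) / rate
  tc <- spike_width_s * 0.5
  s1 <- spike_width_s / 6
  s2 <- spike_width_s / 3
  g <- exp(-(t - tc)^2 / (2 * s1^2)) -
    0.05 * exp(-(t - tc - 2 * s2)^2 / (2 * s2^2))
  spec$amplitude * g / max(abs(g))
}

#' Inject a burst or spike into a recording
#'
#' Adds the waveform in place on the target channel and returns the exact
#' ground-truth marker: label `R` for HFOs below 250 Hz, `F` at or above,
#' `A` for spikes; HFO markers carry a `peak_freq` property.
#'
#' @param rec An `hfo_recording` (single epoch assumed for `epoch_index`).
#' @param spec An [injection_spec()].
#' @param epoch_index Epoch to inject into.
#' @return A list with `recording` and `marker` (one-row `hfo_events`).
#' @export
inject <- function(rec, spec, epoch_index = 1L) {
  ep <- rec$epochs[[epoch_index]]
  ch <- ep[[spec$channel]]
  if (is.null(ch)) stop("inject(): unknown channel '", spec$channel, "'")
  wave <- if (spec$kind == "hfo") hfo_burst_wave(spec, ch$rate)
          else spike_wave(spec, ch$rate)
  dur <- length(wave) / ch$rate
  if (spec$t0 < 0 || spec$t0 + dur > epoch_duration(ep) + 1e-9) {
    stop("inject(): injection [", spec$t0, ", ", spec$t0 + dur,
         ") outside epoch bounds")
  }
  i0 <- sec_to_idx(spec$t0, ch$rate)
  idx <- (i0 + 1L):(i0 + length(wave))
  ch$samples[idx] <- ch$samples[idx] + wave
  ep[[spec$channel]] <- channel(ch$name, ch$rate, ch$samples, ch$unit)
  rec$epochs[[epoch_index]] <- epoch(ep)
  label <- if (spec$kind == "spike") "A" else if (spec$f0 < 250) "R" else "F"
  marker <- event_list(
    epoch_index = epoch_index, channel = spec$channel, onset = spec$t0,
    duration = dur, label = label,
    peak_freq = if (spec$kind == "hfo") spec$f0 else NA_real_)
  list(recording = rec, marker = marker)
}

place_onsets <- function(n, duration_s, event_dur_s, min_gap_s) {
  # rejection sampling of onsets with a minimum onset-to-onset gap
  if (n == 0L) return(numeric())
  span <- duration_s - event_dur_s - 0.1
  if (span <= 0 || n * min_gap_s > span) {
    stop("infeasible event density: ", n, " events with ", min_gap_s,
         " s gaps do not fit in ", duration_s, " s")
  }
  onsets <- numeric(0)
  tries <- 0L
  while (length(onsets) < n) {
    cand <- stats::runif(1, 0.05, 0.05 + span)
    if (!length(onsets) || min(abs(onsets - cand)) >= min_gap_s) {
      onsets <- c(onsets, cand)
    }
    tries <- tries + 1L
    if (tries > 1000L * n) {
      stop("infeasible event density: placement failed after ", tries, " tries")
    }
  }
  sort(onsets)
}

#' Generate a labeled synthetic dataset
#'
#' Produces `n_recordings` independent recordings from one config, each with
#' stochastically placed ripples, fast ripples, and spikes, plus the exact
#' ground-truth event list. HFO amplitudes are `snr` times the in-band SD of
#' the generated background in the event's own band (80-250 or 250-500 Hz);
#' spikes get `snr` times the broadband SD.
#'
#' @param config A [sim_config()] whose `events` field is a
#'   [sim_events_config()].
#' @param n_recordings Number of recordings to generate.
#' @return A list with `recordings` (list of `hfo_recording`) and
#'   `truth` (list of `hfo_events`, one per recording).
#' @export
generate_labeled_dataset <- function(config, n_recordings = 1L) {
  stopifnot(inherits(config, "sim_config"))
  ev <- config$events
  if (is.null(ev)) stop("generate_labeled_dataset(): config$events is NULL")
  recs <- vector("list", n_recordings)
  truths <- vector("list", n_recordings)
  for (r in seq_len(n_recordings)) {
    sub <- config
    sub$seed <- (config$seed + 7919L * (r - 1L)) %% .Machine$integer.max
    rec <- generate_background(sub)
    with_seed(sub$seed + 1L, {
      markers <- list()
      for (k in seq_len(config$n_channels)) {
        chname <- sprintf("CH%02d", k)
        bg <- get_channel(rec, chname)$samples
        n_tot <- ev$n_ripple + ev$n_fast + ev$n_spike
        if (n_tot == 0L) next
        onsets <- place_onsets(n_tot, config$duration_s,
                               max(ev$cycles) / min(ev$ripple_f), ev$min_gap_s)
        kinds <- sample(rep(c("R", "F", "S"),
                            c(ev$n_ripple, ev$n_fast, ev$n_spike)))
        sd_r <- band_sd(bg, config$rate, 80, 250)
        sd_f <- band_sd(bg, config$rate, 250, min(500, config$rate / 2))
        for (j in seq_along(onsets)) {
          spec <- switch(kinds[j],
            R = injection_spec(chname, onsets[j],
                               f0 = stats::runif(1, ev$ripple_f[1], ev$ripple_f[2]),
                               n_cycles = sample(ev$cycles[1]:ev$cycles[2], 1L),
                               amplitude = ev$snr * sd_r),
            F = injection_spec(chname, onsets[j],
                               f0 = stats::runif(1, ev$fast_f[1], ev$fast_f[2]),
                               n_cycles = sample(ev$cycles[1]:ev$cycles[2], 1L),
                               amplitude = ev$snr * sd_f),
            S = injection_spec(chname, onsets[j], kind = "spike",
                               amplitude = ev$snr * stats::sd(bg)))
          out <- inject(rec, spec)
          rec <- out$recording
          markers[[length(markers) + 1L]] <- out$marker
        }
      }
      recs[[r]] <- rec
      truths[[r]] <- if (length(markers)) do.call(bind_events, markers)
                     else event_list()
    })
  }
  list(recordings = recs, truth = truths)
}
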