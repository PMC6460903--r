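# Shared fixture builders. Everything is generated in code at test time.

fix_recording <- function(rate = 256, duration = 1, n_channels = 2,
                          fn = function(t, k) sin(2 * pi * 10 * t) * 50) {
  n <- round(rate * duration)
  t <- (seq_len(n) - 1) / rate
  chans <- lapply(seq_len(n_channels), function(k) {
    channel(sprintf("CH%02d", k), rate, fn(t, k))
  })
  recording(epoch(chans), subject_id = "fixture")
}

# three-class Gaussian features: 2 informative columns (class-mean
# separation `sep` in SD units), the rest pure noise
fix_class_data <- function(n_per = 60, n_noise = 18, sep = 3, seed = 1) {
  set.seed(seed)
  mu <- rbind(c(0, 0), c(sep, 0), c(0, sep))
  n <- 3 * n_per
  x <- matrix(stats::rnorm(n * (2 + n_noise)), ncol = 2 + n_noise)
  for (k in 1:3) {
    rows <- ((k - 1) * n_per + 1):(k * n_per)
    x[rows, 1:2] <- x[rows, 1:2] + rep(mu[k, ], each = n_per)
  }
  colnames(x) <- sprintf("f%02d", seq_len(ncol(x)))
  labels <- rep(c("EOI", "F", "R"), each = n_per)
  ev <- event_list(rep(1L, n), rep("CH01", n),
                   seq(0, by = 0.1, length.out = n), rep(0.05, n), labels)
  list(table = feature_table(x, ev, "syn"), labels = labels)
}

# calibrated detector world: 120 s, 20 ripples at 5x in-band SD
fix_detector_world <- function(seed = 1) {
  cfg <- sim_config(n_channels = 1, duration_s = 120, rate = 2000,
                    seed = seed,
                    events = sim_events_config(n_ripple = 20, n_fast = 0,
                                               n_spike = 0, snr = 5,
                                               min_gap_s = 1))
  ds <- generate_labeled_dataset(cfg)
  filt <- apply_fir(ds$recordings[[1L]],
                    design_fir(80, 250, rate = 2000))
  list(raw = ds$recordings[[1L]], filtered = filt, truth = ds$truth[[1L]])
}

# direct O(N^2) S-transform oracle: Gaussian window f/sqrt(2*pi) in time,
# phase referenced to time zero, periodized over +/- one record
st_direct_oracle <- function(x, rate, f_lo, f_hi) {
  n <- length(x)
  rows <- which((seq_len(n) - 1) * rate / n >= f_lo &
                  (seq_len(n) - 1) * rate / n <= f_hi)
  rows <- rows[rows > 1L]
  out <- matrix(0, length(rows), n)
  for (r in seq_along(rows)) {
    nn <- rows[r] - 1L
    for (j in 0:(n - 1)) {
      acc <- 0 + 0i
      for (k in 0:(n - 1)) {
        d <- j - k
        g <- sum(exp(-(((d + c(-n, 0, n)) * nn / n)^2) / 2))
        acc <- acc + x[k + 1] * g * exp(-2i * pi * nn * k / n)
      }
      out[r, j + 1] <- Mod(acc * nn / (n * sqrt(2 * pi)))
    }
  }
  out
}

digest_samples <- function(rec) {
  lapply(rec$epochs, function(ep) lapply(ep, `[[`, "samples"))
}

sens_prec <- function(truth, detected, min_overlap = 50) {
  m <- match_events(truth, detected, min_overlap)
  c(sensitivity = nrow(m$pairs) / max(1L, nrow(truth)),
    precision = nrow(m$pairs) / max(1L, nrow(detected)))
}
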