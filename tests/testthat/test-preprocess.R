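# Windowed-sinc FIR design/application and EMD.

test_that("FIR kernels meet DC gain and stop-band specifications", {
  lp <- design_fir(high_hz = 100, rate = 1000, taps = 201)
  expect_equal(sum(lp$taps), 1, tolerance = 1e-6)        # unit DC gain
  hp <- design_fir(low_hz = 100, rate = 1000, taps = 201)
  expect_lt(abs(sum(hp$taps)), 1e-6)                     # zero DC gain
  # Blackman window's known floor is ~ -74 dB for a single pass
  bp <- design_fir(80, 250, rate = 2000, taps = 513)
  expect_lte(fir_stopband_db(bp), -70)
  expect_error(design_fir(rate = 1000), "at least one cutoff")
  expect_error(design_fir(600, NULL, rate = 1000), "outside")
  expect_error(design_fir(300, 100, rate = 1000), "low_hz must be")
  expect_error(design_fir(80, 250, rate = 2000, taps = 20), "odd")
})

test_that("self-convolved band-pass kernel reaches -145 dB stop-band", {
  k <- design_fir(80, 250, rate = 2000, taps = 513, self_convolve = TRUE)
  expect_lte(fir_stopband_db(k), -145)
})

test_that("FFT filtering equals direct convolution and is delay-free", {
  set.seed(42)
  x <- stats::rnorm(2000)
  h <- design_fir(80, 250, rate = 2000, taps = 101)$taps
  # oracle: naive O(N*L) time-domain convolution
  direct <- stats::convolve(x, rev(h), type = "open")
  d <- (length(h) - 1L) %/% 2L
  expect_lt(max(abs(fir_filter_signal(x, h) - direct[(d + 1):(d + 2000)])) /
              max(abs(direct)), 1e-9)
  # unit impulse kernel: identity
  expect_equal(fir_filter_signal(x, 1), x)
  rec <- fix_recording(rate = 1000, fn = function(t, k) stats::rnorm(length(t)))
  expect_error(apply_fir(rec, design_fir(80, 250, rate = 2000)), "rate")
})

test_that("band-pass passes in-band tones and rejects out-of-band tones", {
  rate <- 2000
  t <- (0:(4 * rate - 1)) / rate
  k <- design_fir(80, 250, rate = rate, taps = 513)
  mid <- (rate + 1):(3 * rate)                 # steady-state region
  y150 <- fir_filter_signal(sin(2 * pi * 150 * t), k$taps)
  expect_equal(max(abs(y150[mid])), 1, tolerance = 0.01)
  # peak alignment within +/- 1 sample (zero phase after delay compensation)
  x150 <- sin(2 * pi * 150 * t)
  cc <- vapply(-3:3, function(l) {
    sum(x150[mid] * y150[mid + l])
  }, numeric(1))
  expect_lte(abs((-3:3)[which.max(cc)]), 1)
  y20 <- fir_filter_signal(sin(2 * pi * 20 * t), k$taps)
  expect_lt(20 * log10(max(abs(y20[mid]))), -60)
})

test_that("linear-phase property: cross-correlation peak at lag 0", {
  set.seed(9)
  rate <- 2000
  k <- design_fir(80, 250, rate = rate, taps = 257)
  x <- fir_filter_signal(stats::rnorm(4000), k$taps)  # band-limited input
  y <- fir_filter_signal(x, k$taps)
  cc <- stats::ccf(x, y, lag.max = 5, plot = FALSE)
  expect_equal(cc$lag[which.max(cc$acf)], 0)
})

test_that("EMD terminates, reconstructs, and separates a two-tone signal", {
  # linear ramp: no IMFs
  ramp <- emd(seq(0, 1, length.out = 100), rate = 100)
  expect_length(ramp$imfs, 0L)
  expect_equal(ramp$residual, seq(0, 1, length.out = 100))
  # constant input: status flag, residual = input
  cst <- emd(rep(2, 50), rate = 100)
  expect_equal(cst$status, "constant")
  expect_equal(cst$residual, rep(2, 50))
  # completeness and band separation on the two-tone signal
  rate <- 2000
  t <- (1:(2 * rate)) / rate
  x <- sin(2 * pi * 200 * t) + sin(2 * pi * 10 * t)
  dec <- emd(x, rate)
  expect_gt(length(dec$imfs), 0L)
  recon <- Reduce(`+`, dec$imfs) + dec$residual
  expect_lt(max(abs(recon - x)) / max(abs(x)), 1e-8)
  imf1 <- dec$imfs[[1L]]
  hf <- band_sd(imf1, rate, 100, 1000)^2
  tot <- band_sd(imf1, rate, 0.1, 1000)^2
  expect_gte(hf / tot, 0.95)
})

test_that("IMFs have a zero crossing between consecutive extrema", {
  set.seed(4)
  rate <- 1000
  x <- fir_filter_signal(stats::rnorm(2000), design_fir(20, 200, rate = rate,
                                                        taps = 101)$taps)
  dec <- emd(x, rate, max_imfs = 3L)
  for (imf in dec$imfs) {
    ex <- local_extrema(imf)
    pos <- sort(c(ex$maxima, ex$minima))
    bad <- 0L
    for (i in seq_len(length(pos) - 1L)) {
      seg <- imf[pos[i]:pos[i + 1L]]
      if (min(seg) > 0 || max(seg) < 0) bad <- bad + 1L
    }
    # allow a small fraction of violations near the boundary extrema
    expect_lte(bad, ceiling(0.02 * length(pos)))
  }
})

test_that("emd_highpass recomposes the chosen IMF subset", {
  rate <- 2000
  t <- (1:(2 * rate)) / rate
  x <- sin(2 * pi * 200 * t) + sin(2 * pi * 10 * t)
  rec <- recording(epoch(channel("CH01", rate, x)))
  # first_imf = 1, n_imfs = large: output = input - residual
  dec <- emd(x, rate, max_imfs = 12L)
  hp_all <- emd_highpass(rec, 1L, 12L)
  expect_equal(get_channel(hp_all, "CH01")$samples, x - dec$residual,
               tolerance = 1e-10)
  # IMF 1 only: retains the 200 Hz tone, rejects the 10 Hz tone
  hp1 <- emd_highpass(rec, 1L, 1L)
  y <- get_channel(hp1, "CH01")$samples
  e200 <- band_sd(y, rate, 190, 210)^2 / band_sd(x, rate, 190, 210)^2
  e10 <- band_sd(y, rate, 5, 15)^2 / band_sd(x, rate, 5, 15)^2
  expect_gte(e200, 0.90)
  expect_lte(e10, 0.10)
  # zero signal in, zero signal out
  z <- recording(epoch(channel("CH01", rate, numeric(100))))
  expect_equal(get_channel(emd_highpass(z, 1L, 2L), "CH01")$samples,
               numeric(100))
})

test_that("band-pass filtering a spike produces a false-ripple transient", {
  rate <- 2000
  cfg <- sim_config(1, 6, rate, seed = 21)
  rec <- generate_background(cfg)
  bg_inband <- band_sd(get_channel(rec, "CH01")$samples, rate, 80, 250)
  out <- inject(rec, injection_spec("CH01", 3, kind = "spike",
                                    amplitude = 8 * 25))
  filt <- apply_fir(out$recording, design_fir(80, 250, rate = rate))
  env <- hilbert_envelope(get_channel(filt, "CH01")$samples)
  i0 <- floor(2.99 * rate); i1 <- floor(3.03 * rate)
  expect_gt(max(env[i0:i1]), 3 * bg_inband)
})
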