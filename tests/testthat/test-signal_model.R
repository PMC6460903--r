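# Core containers, EDF+ round trips, and segmentation.

test_that("container invariants are enforced", {
  expect_error(channel("a", 0, 1:10), "rate")
  expect_error(channel("a", 100, numeric()), "sample")
  expect_error(epoch(channel("a", 100, 1:100), channel("b", 100, 1:50)),
               "duration")
  # differing rates with equal duration are allowed
  ep <- epoch(channel("a", 100, numeric(100)), channel("b", 200, numeric(200)))
  expect_equal(epoch_duration(ep), 1)
  expect_error(recording(list()), "at least one epoch")
  expect_error(event_list(1L, "a", 0, 0, "EOI"), "duration")
  expect_error(event_list(1L, "a", -1, 1, "EOI"), "onset")
  expect_error(event_list(1L, "a", 0, 1, ""), "label")
})

test_that("event lists stay sorted and validate against recordings", {
  ev <- event_list(c(1L, 1L, 1L), c("b", "a", "a"), c(0.1, 0.5, 0.2),
                   rep(0.05, 3), c("R", "F", "EOI"))
  expect_equal(ev$channel, c("a", "a", "b"))
  expect_equal(ev$onset, c(0.2, 0.5, 0.1))
  rec <- fix_recording(rate = 100, duration = 1, n_channels = 1)
  bad <- event_list(1L, "CH01", 0.9, 0.5, "R")
  expect_error(validate_events(bad, rec), "past epoch end")
  expect_error(validate_events(event_list(1L, "nope", 0.1, 0.1, "R"), rec),
               "unknown channel")
})

test_that("EDF round trip preserves structure and samples to quantization", {
  rec <- fix_recording(rate = 256, duration = 1, n_channels = 2,
                       fn = function(t, k) 100 * sin(2 * pi * 10 * t + k))
  ev <- event_list(c(1L, 1L), c("CH01", "CH02"), c(0.10, 0.55),
                   c(0.05, 0.20), c("R", "F"))
  tf <- withr::local_tempfile(fileext = ".edf")
  write_edf(rec, tf, events = ev)
  back <- read_edf(tf)
  ep <- back$recording$epochs[[1L]]
  expect_equal(names(ep), c("CH01", "CH02"))
  expect_equal(vapply(ep, `[[`, numeric(1), "rate"), c(CH01 = 256, CH02 = 256))
  expect_equal(lengths(lapply(ep, `[[`, "samples")),
               c(CH01 = 256L, CH02 = 256L))
  # 16-bit quantization oracle: step = physical range / 65536
  step <- (3276.8 * 2) / 65536
  for (k in 1:2) {
    expect_lte(max(abs(ep[[k]]$samples - rec$epochs[[1L]][[k]]$samples)),
               step)
  }
  expect_equal(nrow(back$events), 2L)
  expect_equal(back$events$label, ev$label)
  expect_equal(back$events$channel, ev$channel)
  expect_equal(back$events$onset, ev$onset, tolerance = 1e-9)
})

test_that("EDF round-trip property holds for random in-range recordings", {
  step <- (3276.8 * 2) / 65536
  for (seed in 1:4) {
    set.seed(seed)
    rec <- fix_recording(rate = 128, duration = 2, n_channels = 1,
                         fn = function(t, k) stats::rnorm(length(t), 0, 300))
    tf <- withr::local_tempfile(fileext = ".edf")
    write_edf(rec, tf)
    back <- read_edf(tf)
    expect_lte(max(abs(back$recording$epochs[[1L]][[1L]]$samples -
                         rec$epochs[[1L]][[1L]]$samples)), step)
  }
})

test_that("EDF writer handles mixed rates, empty annotations, range errors", {
  ep <- epoch(channel("slow", 256, stats::rnorm(256, 0, 10)),
              channel("fast", 512, stats::rnorm(512, 0, 10)))
  rec <- recording(ep)
  tf <- withr::local_tempfile(fileext = ".edf")
  write_edf(rec, tf)           # zero-length event list
  back <- read_edf(tf)
  expect_equal(back$recording$epochs[[1L]][["slow"]]$rate, 256)
  expect_equal(back$recording$epochs[[1L]][["fast"]]$rate, 512)
  expect_equal(nrow(back$events), 0L)
  # independent header inspection oracle: bytes 252..255 = signal count,
  # samples-per-record fields at offset 256 * (ns + 1) - 32 * ns ... etc.
  hdr <- readBin(tf, "raw", 256L)
  ns <- as.integer(trimws(rawToChar(hdr[253:256])))
  expect_equal(ns, 3L)         # 2 signals + annotations
  shdr <- readBin(con <- file(tf, "rb"), "raw", 256L * (ns + 1L))
  close(con)
  spr_off <- 256L + ns * 216L
  spr <- vapply(seq_len(ns), function(i) {
    as.integer(trimws(rawToChar(shdr[(spr_off + (i - 1L) * 8L + 1L):
                                       (spr_off + i * 8L)])))
  }, integer(1))
  expect_equal(spr[1:2], c(256L, 512L))
  # out-of-range amplitude errors rather than clipping
  big <- recording(epoch(channel("x", 100, rep(4000, 100))))
  expect_error(write_edf(big, tf), "physical range")
})

test_that("read_edf rejects malformed files", {
  tf <- withr::local_tempfile(fileext = ".edf")
  rec <- fix_recording(rate = 100, duration = 1, n_channels = 1)
  write_edf(rec, tf)
  raw <- readBin(tf, "raw", file.info(tf)$size)
  # zero data records
  bad <- raw
  bad[237:244] <- charToRaw(sprintf("%-8s", "0"))
  tf2 <- withr::local_tempfile(fileext = ".edf")
  writeBin(bad, tf2)
  expect_error(read_edf(tf2), "data records")
  # EDF+D dialect
  bad <- raw
  bad[193:200] <- charToRaw(sprintf("%-8s", "EDF+D"))
  writeBin(bad, tf2)
  expect_error(read_edf(tf2), "EDF\\+D")
  # truncated data -> inconsistent record size
  writeBin(raw[1:(length(raw) - 10L)], tf2)
  expect_error(read_edf(tf2), "inconsistent")
})

test_that("segment_by_time honors half-open windows and conserves samples", {
  rec <- fix_recording(rate = 1000, duration = 4, n_channels = 1,
                       fn = function(t, k) seq_along(t))
  full <- segment_by_time(rec, list(c(0, 4)))
  expect_identical(full$epochs[[1L]][[1L]]$samples,
                   rec$epochs[[1L]][[1L]]$samples)
  seg <- segment_by_time(rec, list(c(1, 2)))
  expect_length(seg$epochs[[1L]][[1L]]$samples, 1000L)
  # conservation across a partition
  parts <- segment_by_time(rec, list(c(0, 1.25), c(1.25, 2.5), c(2.5, 4)))
  expect_equal(sum(vapply(parts$epochs,
                          function(e) length(e[[1L]]$samples), integer(1))),
               4000L)
  expect_error(segment_by_time(rec, list(c(0.5, 10))), "past recording end")
  expect_error(segment_by_time(rec, list(c(2, 1))), "invalid window")
})

test_that("segment_by_events creates per-event epochs with clipping flags", {
  rec <- fix_recording(rate = 1000, duration = 3, n_channels = 1)
  ev <- event_list(rep(1L, 3), rep("CH01", 3), c(0.0, 1.0, 2.0),
                   rep(0.05, 3), c("R", "R", "F"))
  out <- segment_by_events(rec, ev, "R", pre_s = 0.5, post_s = 0.5)
  expect_equal(n_epochs(out$recording), 2L)
  expect_true(out$clipped[1L])       # clipped at recording start
  expect_false(out$clipped[2L])
  expect_length(out$recording$epochs[[2L]][[1L]]$samples, 1000L)
  expect_warning(res <- segment_by_events(rec, ev, "X", 0.1, 0.1),
                 "no events matched")
  expect_null(res$recording)
})

test_that("marker tables round-trip through CSV and JSON", {
  ev <- event_list(c(1L, 2L), c("a", "b"), c(0.5, 1.25), c(0.1, 0.2),
                   c("R", "F"), peak_freq = c(120, 320))
  for (ext in c(".csv", ".json")) {
    tf <- withr::local_tempfile(fileext = ext)
    write_markers(ev, tf)
    back <- read_markers(tf)
    expect_equal(back$onset, ev$onset)
    expect_equal(back$label, ev$label)
    expect_equal(back$peak_freq, ev$peak_freq)
  }
})
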