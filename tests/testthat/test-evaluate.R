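# Event matching, counters/metrics, HFO report, correlation assessment.

test_that("match_events handles identity, boundary, and channel cases", {
  ev <- event_list(c(1L, 1L), c("a", "b"), c(0.1, 0.3), c(0.1, 0.1),
                   c("R", "F"))
  m <- match_events(ev, ev, 50)
  expect_equal(nrow(m$pairs), 2L)
  expect_true(all(m$pairs$overlap == 1))
  expect_length(m$unmatched_reference, 0L)
  # reference [0, 100) vs test [50, 150) ms: 50% overlap exactly
  ref <- event_list(1L, "a", 0.00, 0.1, "R")
  tst <- event_list(1L, "a", 0.05, 0.1, "EOI")
  expect_equal(nrow(match_events(ref, tst, 50)$pairs), 1L)
  expect_equal(nrow(match_events(ref, tst, 51)$pairs), 0L)
  # same interval, different channel: unmatched
  other <- event_list(1L, "b", 0.00, 0.1, "EOI")
  expect_equal(nrow(match_events(ref, other, 10)$pairs), 0L)
})

test_that("matching conserves events and is monotone in the threshold", {
  set.seed(14)
  mk <- function(n) {
    event_list(rep(1L, n), sample(c("a", "b"), n, TRUE),
               stats::runif(n, 0, 9), stats::runif(n, 0.02, 0.3),
               rep("R", n))
  }
  ref <- mk(25); tst <- mk(30)
  prev <- Inf
  for (thr in c(10, 30, 50, 70, 90)) {
    m <- match_events(ref, tst, thr)
    expect_equal(nrow(m$pairs) + length(m$unmatched_reference), nrow(ref))
    expect_equal(nrow(m$pairs) + length(m$unmatched_test), nrow(tst))
    expect_true(all(m$pairs$overlap > 0 & m$pairs$overlap <= 1))
    expect_true(!anyDuplicated(m$pairs$reference_row))
    expect_true(!anyDuplicated(m$pairs$test_row))
    expect_lte(nrow(m$pairs), prev)
    prev <- nrow(m$pairs)
  }
})

test_that("compute_metrics reproduces the formulas and conventions", {
  cnt <- data.frame(class = "R", P_T = 8L, P_F = 4L, N_F = 2L)
  m <- compute_metrics(cnt)["R", ]
  expect_equal(round(m$sensitivity, 3), 0.8)
  expect_equal(round(m$precision, 3), 0.667)
  expect_equal(round(m$fdr, 3), 0.333)
  expect_equal(round(m$f1, 3), 0.727)
  expect_equal(m$fnr, 1 - m$sensitivity)
  # 0/0 ratios are missing, not zero
  z <- compute_metrics(data.frame(class = "R", P_T = 0L, P_F = 0L, N_F = 0L))
  expect_true(all(is.na(z["R", c("sensitivity", "precision", "fdr", "f1")])))
  # precision + FDR = 1 whenever defined
  set.seed(2)
  for (i in 1:10) {
    cnt <- data.frame(class = "x", P_T = sample(0:9, 1),
                      P_F = sample(0:9, 1), N_F = sample(0:9, 1))
    mm <- compute_metrics(cnt)["x", ]
    if (!is.na(mm$precision)) expect_equal(mm$precision + mm$fdr, 1)
  }
})

test_that("counters are built correctly from label comparisons", {
  truth <- c("R", "R", "F", "F", "A", "R", "A", "F", "R", "R")
  pred <- c("R", "F", "F", "F", "A", "R", "R", "A", "R", "R")
  cnt <- counters_from_labels(truth, pred)
  expect_equal(cnt["R", "P_T"], 4L)
  expect_equal(cnt["R", "N_F"], 1L)
  expect_equal(cnt["R", "P_F"], 1L)
  expect_equal(cnt["F", "P_T"], 2L)
  expect_equal(sum(cnt$P_T) + sum(cnt$N_F), length(truth))
  expect_equal(sum(cnt$N_F), sum(cnt$P_F))
  # perfect predictions
  p <- compute_metrics(counters_from_labels(truth, truth))
  per <- p[p$class != "micro", ]
  expect_true(all(per$sensitivity == 1 & per$precision == 1 & per$f1 == 1 &
                    per$fdr == 0))
})

test_that("hfo_report summarizes counts, durations, IEI, and occupancy", {
  rec <- fix_recording(rate = 100, duration = 4, n_channels = 2)
  ev <- event_list(rep(1L, 3), rep("CH01", 3), c(0.0, 1.0, 2.0),
                   rep(0.1, 3), rep("R", 3))
  rep1 <- hfo_report(ev, rec, bin_s = 1)
  row <- rep1$summary[rep1$summary$channel == "CH01" &
                        rep1$summary$label == "R", ]
  expect_equal(row$count, 3L)
  expect_equal(row$mean_duration_ms, 100)
  expect_equal(row$mean_iei_s, 0.9)           # offset-to-onset convention
  expect_equal(unname(rep1$occurrence["CH01", ]), c(1L, 1L, 1L, 0L))
  # single event: IEI missing
  one <- hfo_report(event_list(1L, "CH02", 0.5, 0.1, "F"), rec)
  expect_true(is.na(one$summary$mean_iei_s[
    one$summary$channel == "CH02" & one$summary$label == "F"]))
  # per-channel percentages sum to 100
  mixed <- bind_events(ev, event_list(1L, "CH01", 3.0, 0.1, "F"))
  rep2 <- hfo_report(mixed, rec)
  pc <- rep2$summary[rep2$summary$channel == "CH01", "pct"]
  expect_equal(sum(pc), 100, tolerance = 0.01)
})

test_that("correlation_report splits, matches, and derives metrics", {
  ev_ref <- event_list(rep(1L, 3), rep("a", 3), c(1, 2, 3), rep(0.1, 3),
                       rep("R", 3))
  ev_tst <- ev_ref
  ev_tst$label <- "auto"
  both <- bind_events(ev_ref, ev_tst)
  cr <- correlation_report(both, "R", "auto", 50)
  expect_equal(cr$metrics$sensitivity, 1)
  expect_equal(cr$metrics$precision, 1)
  # disjoint events: all counters zero on the TP side
  far <- event_list(rep(1L, 2), rep("a", 2), c(5, 6), rep(0.1, 2),
                    rep("auto", 2))
  cr2 <- correlation_report(bind_events(ev_ref, far), "R", "auto", 50)
  expect_equal(cr2$counters$P_T, 0L)
  expect_equal(cr2$counters$P_F, 2L)
  expect_equal(cr2$counters$N_F, 3L)
  expect_error(correlation_report(both, c("R", "auto"), "auto", 50),
               "overlap")
})

test_that("correlation metrics agree with an O(n^2) brute-force matcher", {
  # fixture designed without ambiguous double-overlaps: events on a grid
  set.seed(33)
  onsets <- seq(0.5, 15, by = 0.5)
  keep_r <- sample(c(TRUE, FALSE), length(onsets), TRUE)
  keep_t <- sample(c(TRUE, FALSE), length(onsets), TRUE)
  ref <- event_list(rep(1L, sum(keep_r)), rep("a", sum(keep_r)),
                    onsets[keep_r], rep(0.2, sum(keep_r)), rep("R", sum(keep_r)))
  tst <- event_list(rep(1L, sum(keep_t)), rep("a", sum(keep_t)),
                    onsets[keep_t] + 0.05, rep(0.2, sum(keep_t)),
                    rep("auto", sum(keep_t)))
  cr <- correlation_report(bind_events(ref, tst), "R", "auto", 50)
  # brute force: count reference events with any >= 50% overlap test event
  brute_tp <- 0L
  for (i in seq_len(nrow(ref))) {
    for (j in seq_len(nrow(tst))) {
      ov <- min(ref$onset[i] + 0.2, tst$onset[j] + 0.2) -
        max(ref$onset[i], tst$onset[j])
      if (ov / 0.2 >= 0.5) { brute_tp <- brute_tp + 1L; break }
    }
  }
  expect_equal(cr$counters$P_T, brute_tp)
  expect_equal(cr$metrics$sensitivity, brute_tp / nrow(ref))
})

test_that("swapping reference and test swaps sensitivity and precision", {
  set.seed(44)
  n <- 15
  ref <- event_list(rep(1L, n), rep("a", n), stats::runif(n, 0, 20),
                    rep(0.15, n), rep("R", n))
  m <- 12
  tst <- event_list(rep(1L, m), rep("a", m), stats::runif(m, 0, 20),
                    rep(0.15, m), rep("auto", m))
  both <- bind_events(ref, tst)
  a <- correlation_report(both, "R", "auto", 50)$metrics
  b <- correlation_report(both, "auto", "R", 50)$metrics
  expect_equal(a$sensitivity, b$precision)
  expect_equal(a$precision, b$sensitivity)
})
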