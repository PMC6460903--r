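# Event matching, detection/classification statistics, HFO activity report,
# and reference-vs-test correlation assessment.

overlap_fraction <- function(on1, dur1, on2, dur2) {
  ov <- min(on1 + dur1, on2 + dur2) - max(on1, on2)
  if (ov <= 0) return(0)
  min(1, ov / min(dur1, dur2))  # shorter-event normalization: containment = 1
}

#' Match reference and test events by channel and temporal overlap
#'
#' Candidate pairs require identical channel and epoch; the overlap
#' fraction is the overlap duration divided by the shorter event's
#' duration. Matching is greedy one-to-one in descending overlap order
#' (ties: earlier reference onset); pairs below `min_overlap_pct` are
#' discarded.
#'
#' @param reference,test `hfo_events` lists.
#' @param min_overlap_pct Threshold in percent, `0 < pct <= 100`.
#' @return An `hfo_match`: `pairs` (data frame with `reference_row`,
#'   `test_row`, `overlap`), `unmatched_reference`, `unmatched_test` (row
#'   indices).
#' @export
match_events <- function(reference, test, min_overlap_pct = 50) {
  stopifnot(min_overlap_pct > 0, min_overlap_pct <= 100)
  thr <- min_overlap_pct / 100
  cand <- list()
  for (i in seq_len(nrow(reference))) {
    sel <- which(test$channel == reference$channel[i] &
                   test$epoch_index == reference$epoch_index[i])
    for (j in sel) {
      ov <- overlap_fraction(reference$onset[i], reference$duration[i],
                             test$onset[j], test$duration[j])
      if (ov >= thr - 1e-12) {
        cand[[length(cand) + 1L]] <- c(i, j, ov)
      }
    }
  }
  pairs <- data.frame(reference_row = integer(), test_row = integer(),
                      overlap = numeric())
  if (length(cand)) {
    cm <- do.call(rbind, cand)
    ord <- order(-cm[, 3L], reference$onset[cm[, 1L]], cm[, 1L], cm[, 2L])
    cm <- cm[ord, , drop = FALSE]
    used_r <- logical(nrow(reference)); used_t <- logical(nrow(test))
    for (k in seq_len(nrow(cm))) {
      i <- cm[k, 1L]; j <- cm[k, 2L]
      if (used_r[i] || used_t[j]) next
      used_r[i] <- TRUE; used_t[j] <- TRUE
      pairs <- rbind(pairs, data.frame(reference_row = i, test_row = j,
                                       overlap = cm[k, 3L]))
    }
  }
  structure(list(pairs = pairs,
                 unmatched_reference = setdiff(seq_len(nrow(reference)),
                                               pairs$reference_row),
                 unmatched_test = setdiff(seq_len(nrow(test)),
                                          pairs$test_row)),
            class = "hfo_match")
}

#' Build per-class counters from true and predicted labels
#'
#' A correct prediction increments the class's true-positive counter
#' `P_T`; a wrong one increments the true class's false-negative `N_F` and
#' the predicted class's false-positive `P_F`.
#'
#' @param truth,predicted Character label vectors of equal length.
#' @return An `hfo_counters` data frame (one row per class).
#' @export
counters_from_labels <- function(truth, predicted) {
  truth <- as.character(truth); predicted <- as.character(predicted)
  stopifnot(length(truth) == length(predicted))
  classes <- sort(unique(c(truth, predicted)), method = "radix")
  out <- data.frame(class = classes, P_T = 0L, P_F = 0L, N_F = 0L,
                    stringsAsFactors = FALSE)
  rownames(out) <- classes
  for (i in seq_along(truth)) {
    if (truth[i] == predicted[i]) {
      out[truth[i], "P_T"] <- out[truth[i], "P_T"] + 1L
    } else {
      out[truth[i], "N_F"] <- out[truth[i], "N_F"] + 1L
      out[predicted[i], "P_F"] <- out[predicted[i], "P_F"] + 1L
    }
  }
  class(out) <- c("hfo_counters", "data.frame")
  out
}

#' Derived metrics from per-class counters
#'
#' Sensitivity `P_T / (P_T + N_F)`, precision (PPV) `P_T / (P_T + P_F)`,
#' false discovery rate `P_F / (P_T + P_F)`, false negative rate
#' `1 - sensitivity`, and F1 `2 * prec * sens / (prec + sens)`. Undefined
#' 0/0 ratios are reported as `NA`, not 0. A `micro` row aggregates the
#' counters before the division.
#'
#' @param counters An `hfo_counters` data frame (or one with columns
#'   `class`, `P_T`, `P_F`, `N_F`).
#' @return A data frame of per-class metrics plus the micro-average row.
#' @export
compute_metrics <- function(counters) {
  one <- function(pt, pf, nf) {
    sens <- if (pt + nf == 0) NA_real_ else pt / (pt + nf)
    prec <- if (pt + pf == 0) NA_real_ else pt / (pt + pf)
    fdr <- if (pt + pf == 0) NA_real_ else pf / (pt + pf)
    f1 <- if (is.na(sens) || is.na(prec) || sens + prec == 0) NA_real_
          else 2 * prec * sens / (prec + sens)
    c(sensitivity = sens, precision = prec, fdr = fdr,
      fnr = if (is.na(sens)) NA_real_ else 1 - sens, f1 = f1)
  }
  rows <- lapply(seq_len(nrow(counters)), function(i) {
    one(counters$P_T[i], counters$P_F[i], counters$N_F[i])
  })
  out <- as.data.frame(do.call(rbind, rows))
  out <- cbind(class = counters$class, out)
  micro <- one(sum(counters$P_T), sum(counters$P_F), sum(counters$N_F))
  out <- rbind(out, cbind(class = "micro", as.data.frame(t(micro))))
  rownames(out) <- out$class
  out
}

#' HFO activity report
#'
#' Per channel and label: event count, percentage of the channel's total,
#' mean duration (ms), and mean inter-event interval (previous offset to
#' next onset, seconds; `NA` with fewer than two events). Also returns a
#' channel x time occurrence matrix at `bin_s` resolution (events counted
#' at their onset bin).
#'
#' @param events An `hfo_events` list.
#' @param rec The `hfo_recording` the events refer to.
#' @param bin_s Time-bin width for the occurrence map, seconds.
#' @return An `hfo_report`: `summary` data frame and `occurrence` matrix.
#' @export
hfo_report <- function(events, rec, bin_s = 1) {
  validate_events(events, rec)
  chans <- unique(unlist(lapply(rec$epochs, names)))
  rows <- list()
  for (ch in chans) {
    ev_ch <- events[events$channel == ch, , drop = FALSE]
    total <- nrow(ev_ch)
    for (lb in sort(unique(ev_ch$label), method = "radix")) {
      ev <- ev_ch[ev_ch$label == lb, , drop = FALSE]
      iei <- NA_real_
      if (nrow(ev) >= 2L) {
        o <- order(ev$epoch_index, ev$onset)
        ev <- ev[o, , drop = FALSE]
        same <- diff(ev$epoch_index) == 0
        gaps <- (ev$onset[-1L] - (ev$onset + ev$duration)[-nrow(ev)])[same]
        iei <- if (length(gaps)) mean(gaps) else NA_real_
      }
      rows[[length(rows) + 1L]] <- data.frame(
        channel = ch, label = lb, count = nrow(ev),
        pct = 100 * nrow(ev) / total,
        mean_duration_ms = mean(ev$duration) * 1000,
        mean_iei_s = iei, stringsAsFactors = FALSE)
    }
  }
  total_dur <- max(vapply(rec$epochs, epoch_duration, numeric(1)))
  n_bins <- max(1L, as.integer(ceiling(total_dur / bin_s)))
  occ <- matrix(0L, length(chans), n_bins,
                dimnames = list(chans, sprintf("t%03d", seq_len(n_bins))))
  for (i in seq_len(nrow(events))) {
    b <- min(n_bins, 1L + as.integer(floor(events$onset[i] / bin_s)))
    occ[events$channel[i], b] <- occ[events$channel[i], b] + 1L
  }
  summary_df <- if (length(rows)) do.call(rbind, rows) else
    data.frame(channel = character(), label = character(), count = integer(),
               pct = numeric(), mean_duration_ms = numeric(),
               mean_iei_s = numeric())
  structure(list(summary = summary_df, occurrence = occ, bin_s = bin_s),
            class = "hfo_report")
}

#' @export
print.hfo_report <- function(x, ...) {
  cat("<hfo_report>\n")
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Reference-vs-test correlation assessment
#'
#' Splits one event list by label into a reference and a test subset,
#' matches them with [match_events()], and derives the detection counters
#' (`P_T` = matched pairs, `P_F` = unmatched test, `N_F` = unmatched
#' reference) and metrics, plus temporal and channel coverage summaries.
#'
#' @param events An `hfo_events` list.
#' @param reference_labels,test_labels Disjoint non-empty label sets.
#' @param min_overlap_pct Overlap threshold in percent.
#' @return A `correlation_report` list.
#' @export
correlation_report <- function(events, reference_labels, test_labels,
                               min_overlap_pct = 50) {
  stopifnot(length(reference_labels) >= 1L, length(test_labels) >= 1L)
  if (length(intersect(reference_labels, test_labels))) {
    stop("correlation_report(): label partitions overlap: ",
         paste(intersect(reference_labels, test_labels), collapse = ", "))
  }
  ref <- as_event_list(events[events$label %in% reference_labels, , drop = FALSE])
  tst <- as_event_list(events[events$label %in% test_labels, , drop = FALSE])
  m <- match_events(ref, tst, min_overlap_pct)
  pt <- nrow(m$pairs)
  counters <- data.frame(class = "event", P_T = pt,
                         P_F = length(m$unmatched_test),
                         N_F = length(m$unmatched_reference))
  metrics <- compute_metrics(counters)["event", ]
  coverage <- function(ev) {
    list(n = nrow(ev), total_duration_s = sum(ev$duration),
         channels = sort(unique(ev$channel), method = "radix"))
  }
  structure(list(match = m, counters = counters, metrics = metrics,
                 reference_coverage = coverage(ref),
                 test_coverage = coverage(tst)),
            class = "correlation_report")
}

#' @export
print.correlation_report <- function(x, ...) {
  cat("<correlation_report> TP:", x$counters$P_T,
      "FP:", x$counters$P_F, "FN:", x$counters$N_F, "\n")
  print(x$metrics, row.names = FALSE)
  invisible(x)
}
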