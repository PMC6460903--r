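# Per-event feature extraction. Time units inside features are milliseconds
# (the clinical convention for HFO durations); amplitudes stay in the
# channel unit. Standard deviations use the population form (divide by n).

#' Construct a feature table
#'
#' @param values Numeric events x features matrix with column names.
#' @param events The `hfo_events` rows the rows refer to (event keys).
#' @param id Table identifier used as a prefix on concatenation.
#' @return A `feature_table`.
#' @export
feature_table <- function(values, events, id = "ft") {
  values <- as.matrix(values)
  if (is.null(colnames(values))) stop("feature_table(): values need column names")
  if (anyDuplicated(colnames(values))) stop("feature_table(): duplicate feature names")
  if (nrow(values) != nrow(events)) {
    stop("feature_table(): one row per event required")
  }
  if (nrow(values) && any(!is.finite(values))) {
    stop("feature_table(): non-finite feature values")
  }
  structure(list(values = values, events = events, id = id),
            class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  cat("<feature_table>", x$id, ":", nrow(x$values), "event(s) x",
      ncol(x$values), "feature(s)\n")
  invisible(x)
}

#' @export
dim.feature_table <- function(x) dim(x$values)

time_feature_names <- c("mAmp", "dAmp", "dtEx", "dur", "gdPos", "gdNeg",
                        "rmaxA", "rminA", "linLen", "numEx", "sdAEx", "sdDtEx")

sd_pop <- function(x) {
  if (length(x) < 1L) return(0)
  sqrt(mean((x - mean(x))^2))
}

event_segment <- function(rec, ev_row) {
  ch <- get_channel(rec, ev_row$channel, ev_row$epoch_index)
  i0 <- sec_to_idx(ev_row$onset, ch$rate)
  i1 <- sec_to_idx(ev_row$onset + ev_row$duration, ch$rate)
  n <- length(ch$samples)
  if (i0 < 0L || i1 > n || i1 <= i0) {
    stop("event at onset ", ev_row$onset, " s on '", ev_row$channel,
         "' is out of bounds")
  }
  list(x = ch$samples[(i0 + 1L):i1], rate = ch$rate)
}

compute_time_features <- function(x, rate, selection) {
  ex <- local_extrema(x)
  all_ex <- sort(c(ex$maxima, ex$minima))
  dt_ms <- if (length(all_ex) >= 2L) diff(all_ex) / rate * 1000 else numeric()
  a <- mean(x)
  # steepest min->max / max->min transitions among consecutive extrema
  gd_pos <- 0; gd_neg <- 0
  if (length(all_ex) >= 2L) {
    is_max <- all_ex %in% ex$maxima
    for (i in seq_len(length(all_ex) - 1L)) {
      da <- x[all_ex[i + 1L]] - x[all_ex[i]]
      dt <- (all_ex[i + 1L] - all_ex[i]) / rate * 1000
      g <- da / dt
      if (!is_max[i] && is_max[i + 1L]) gd_pos <- max(gd_pos, g)
      if (is_max[i] && !is_max[i + 1L]) gd_neg <- min(gd_neg, g)
    }
  }
  vals <- c(
    mAmp = a,
    dAmp = max(x) - min(x),
    dtEx = if (length(dt_ms)) mean(dt_ms) else 0,
    dur = length(x) / rate * 1000,
    gdPos = gd_pos,
    gdNeg = gd_neg,
    rmaxA = max(x) - a,
    rminA = min(x) - a,
    linLen = sum(abs(diff(x))),
    numEx = length(all_ex),
    sdAEx = if (length(all_ex)) sd_pop(x[all_ex] - a) else 0,
    sdDtEx = if (length(dt_ms)) sd_pop(dt_ms) else 0
  )
  vals[selection]
}

#' Extract time-domain features per event
#'
#' The twelve morphological features: mean amplitude (`mAmp`), peak-to-peak
#' (`dAmp`), mean inter-extremum time in ms (`dtEx`), duration in ms
#' (`dur`), steepest min-to-max and max-to-min gradients (`gdPos`,
#' `gdNeg`), max/min amplitude relative to the mean (`rmaxA`, `rminA`),
#' line length (`linLen`), extremum count (`numEx`), population SD of
#' extremum amplitudes about the mean (`sdAEx`) and of inter-extremum times
#' (`sdDtEx`).
#'
#' @param events `hfo_events` rows, all within `rec`.
#' @param rec The `hfo_recording` the events reference (typically a
#'   filtered version; the extractor can be instantiated several times on
#'   different inputs).
#' @param selection Subset of the twelve names; default all.
#' @param id Table identifier.
#' @return A `feature_table`.
#' @export
extract_time_features <- function(events, rec, selection = time_feature_names,
                                  id = "time") {
  stopifnot(length(selection) >= 1L, all(selection %in% time_feature_names))
  vals <- matrix(0, nrow(events), length(selection),
                 dimnames = list(NULL, selection))
  for (i in seq_len(nrow(events))) {
    seg <- event_segment(rec, events[i, ])
    vals[i, ] <- compute_time_features(seg$x, seg$rate, selection)
  }
  feature_table(vals, events, id)
}

#' Tukey (tapered cosine) window
#' @param n Window length.
#' @param alpha Fraction of the window inside the cosine tapers.
#' @return Numeric window of length `n`.
#' @export
tukey_window <- function(n, alpha = 0.5) {
  if (n == 1L) return(1)
  if (alpha <= 0) return(rep(1, n))
  k <- seq_len(n) - 1
  w <- rep(1, n)
  edge <- alpha * (n - 1) / 2
  lo <- k < edge
  hi <- k > (n - 1) * (1 - alpha / 2)
  w[lo] <- 0.5 * (1 + cos(pi * (k[lo] / edge - 1)))
  w[hi] <- 0.5 * (1 + cos(pi * ((k[hi] - (n - 1) * (1 - alpha / 2)) / edge)))
  w
}

#' Extract binned magnitude-spectrum features per event
#'
#' Each event segment is Tukey-windowed (alpha = 0.5), the FFT magnitude
#' spectrum is computed, and magnitudes are summed into
#' `ceiling((f_hi - f_lo) / bin_hz)` half-open frequency bins
#' `[f, f + bin_hz)`. With `normalize = TRUE`, bins are divided by their
#' maximum and the maximum is appended as feature `specScale` (0 for
#' zero-energy segments, bins left at 0).
#'
#' @param events `hfo_events` rows within `rec`.
#' @param rec The `hfo_recording`.
#' @param f_lo,f_hi Band limits, `f_lo < f_hi <= rate/2`.
#' @param bin_hz Bin width, Hz.
#' @param normalize Normalize bins to `[0, 1]` and append `specScale`.
#' @param alpha Tukey taper fraction.
#' @param id Table identifier.
#' @return A `feature_table`.
#' @export
extract_spectral_features <- function(events, rec, f_lo = 0, f_hi = 500,
                                      bin_hz = 10, normalize = TRUE,
                                      alpha = 0.5, id = "spec") {
  stopifnot(f_lo < f_hi, bin_hz > 0)
  n_bins <- as.integer(ceiling((f_hi - f_lo) / bin_hz - 1e-9))
  bin_names <- sprintf("specBin%03d", seq_len(n_bins))
  cols <- c(bin_names, if (normalize) "specScale")
  vals <- matrix(0, nrow(events), length(cols), dimnames = list(NULL, cols))
  for (i in seq_len(nrow(events))) {
    seg <- event_segment(rec, events[i, ])
    if (f_hi > seg$rate / 2 + 1e-9) {
      stop("extract_spectral_features(): f_hi above Nyquist for event ", i)
    }
    x <- seg$x * tukey_window(length(seg$x), alpha)
    n <- length(x)
    mags <- Mod(stats::fft(x))[seq_len(n %/% 2 + 1L)]
    f <- (seq_len(n %/% 2 + 1L) - 1) * seg$rate / n
    sel <- f >= f_lo & f < f_hi
    bin_of <- floor((f[sel] - f_lo) / bin_hz) + 1L
    bins <- numeric(n_bins)
    if (any(sel)) {
      agg <- tapply(mags[sel], bin_of, sum)
      bins[as.integer(names(agg))] <- agg
    }
    if (normalize) {
      mx <- max(bins)
      if (mx > 0) bins <- bins / mx
      vals[i, ] <- c(bins, mx)
    } else {
      vals[i, ] <- bins
    }
  }
  feature_table(vals, events, id)
}

#' Column-wise concatenation of feature tables
#'
#' All tables must refer to identical event keys in identical order; names
#' are prefixed with each table's identifier to guarantee uniqueness.
#'
#' @param tables A list of `feature_table`s.
#' @return A single `feature_table`.
#' @export
concat_features <- function(tables) {
  stopifnot(length(tables) >= 1L)
  if (length(tables) == 1L) return(tables[[1L]])
  key_cols <- c("epoch_index", "channel", "onset", "duration")
  ref <- as.data.frame(tables[[1L]]$events)[, key_cols]
  for (t in tables[-1L]) {
    k <- as.data.frame(t$events)[, key_cols]
    if (!isTRUE(all.equal(ref, k, check.attributes = FALSE))) {
      stop("concat_features(): event keys differ between tables")
    }
  }
  mats <- lapply(tables, function(t) {
    m <- t$values
    colnames(m) <- paste(t$id, colnames(m), sep = ".")
    m
  })
  feature_table(do.call(cbind, mats), tables[[1L]]$events, id = "concat")
}

#' Read / write feature tables as CSV
#'
#' The CSV carries the event key columns first, then one column per
#' feature.
#'
#' @param ft A `feature_table`.
#' @param path Output path (`.csv` or `.json`).
#' @return `path`, invisibly.
#' @export
write_features <- function(ft, path) {
  df <- cbind(as.data.frame(ft$events)[, c("epoch_index", "channel", "onset",
                                           "duration", "label")],
              as.data.frame(ft$values))
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(df, path, dataframe = "rows", digits = NA)
  } else {
    utils::write.csv(df, path, row.names = FALSE)
  }
  invisible(path)
}
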