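# Coordinate conventions: times in seconds, sample indices 0-based, intervals
# half-open [start, end); seconds -> samples uses floor at both interval ends.

sec_to_idx <- function(t, rate) as.integer(floor(t * rate + 1e-9))

#' Extract time-windowed segments from a recording
#'
#' Produces one contiguous output epoch per requested window. Windows are
#' half-open `[start, end)` in seconds relative to the epoch start; the
#' sample interval is `[floor(start*rate), floor(end*rate))`.
#'
#' @param rec An `hfo_recording`.
#' @param windows A list of `c(start_s, end_s)` pairs (or an n x 2 matrix).
#' @param epoch_index Which input epoch the windows refer to.
#' @return An `hfo_recording` with one epoch per window.
#' @export
segment_by_time <- function(rec, windows, epoch_index = 1L) {
  if (is.matrix(windows)) windows <- asplit(windows, 1L)
  if (!length(windows)) stop("segment_by_time(): no windows given")
  ep <- rec$epochs[[epoch_index]]
  dur <- epoch_duration(ep)
  eps <- lapply(windows, function(w) {
    start <- w[[1L]]; end <- w[[2L]]
    if (start < 0 || end <= start) {
      stop("segment_by_time(): invalid window [", start, ", ", end, ")")
    }
    if (end > dur + 1e-9) {
      stop("segment_by_time(): window [", start, ", ", end,
           ") extends past recording end (", dur, " s)")
    }
    chans <- lapply(ep, function(ch) {
      i0 <- sec_to_idx(start, ch$rate)
      i1 <- sec_to_idx(end, ch$rate)
      channel(ch$name, ch$rate, ch$samples[(i0 + 1L):i1], ch$unit)
    })
    epoch(chans)
  })
  recording(eps, subject_id = rec$subject_id, start_time = rec$start_time)
}

#' Extract event-anchored segments from a recording
#'
#' Creates one output epoch per event whose label is in `selected_labels`,
#' spanning `[onset - pre_s, onset + post_s)` clipped to the epoch bounds.
#' Clipped epochs are flagged in the result.
#'
#' @param rec An `hfo_recording`.
#' @param events An `hfo_events` list.
#' @param selected_labels Labels to segment around (non-empty).
#' @param pre_s,post_s Context before/after the event onset, seconds, >= 0.
#' @return A list with `recording` (one epoch per matching event; zero
#'   epochs are represented as `NULL` with a warning), `clipped` (logical
#'   per epoch) and `source_events` (the matching rows).
#' @export
segment_by_events <- function(rec, events, selected_labels, pre_s, post_s) {
  stopifnot(pre_s >= 0, post_s >= 0, length(selected_labels) >= 1L)
  sel <- events[events$label %in% selected_labels, , drop = FALSE]
  if (!nrow(sel)) {
    warning("segment_by_events(): no events matched labels ",
            paste(selected_labels, collapse = ", "))
    return(list(recording = NULL, clipped = logical(),
                source_events = as_event_list(sel)))
  }
  eps <- vector("list", nrow(sel))
  clipped <- logical(nrow(sel))
  for (i in seq_len(nrow(sel))) {
    ep <- rec$epochs[[sel$epoch_index[i]]]
    dur <- epoch_duration(ep)
    start <- sel$onset[i] - pre_s
    end <- sel$onset[i] + post_s
    if (start < 0) { start <- 0; clipped[i] <- TRUE }
    if (end > dur) { end <- dur; clipped[i] <- TRUE }
    chans <- lapply(ep, function(ch) {
      i0 <- sec_to_idx(start, ch$rate)
      i1 <- sec_to_idx(end, ch$rate)
      channel(ch$name, ch$rate, ch$samples[(i0 + 1L):i1], ch$unit)
    })
    eps[[i]] <- epoch(chans)
  }
  list(recording = recording(eps, subject_id = rec$subject_id),
       clipped = clipped, source_events = as_event_list(sel))
}
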