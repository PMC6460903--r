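#' Construct a channel
#'
#' A channel is a single uniformly sampled signal trace: a name, a sampling
#' rate in samples per second, an amplitude vector (conventionally in
#' microvolts) and a unit string.
#'
#' @param name Channel identifier (non-empty string).
#' @param rate Sampling rate in samples per second, strictly positive.
#' @param samples Numeric vector of amplitudes, length >= 1.
#' @param unit Unit string, default `"uV"`.
#' @return An object of class `hfo_channel`.
#' @export
channel <- function(name, rate, samples, unit = "uV") {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  stopifnot(is.numeric(rate), length(rate) == 1L, rate > 0)
  samples <- as.numeric(samples)
  if (length(samples) < 1L) stop("channel '", name, "': needs at least one sample")
  if (anyNA(samples)) stop("channel '", name, "': samples contain NA")
  structure(
    list(name = name, rate = as.numeric(rate), samples = samples, unit = unit),
    class = "hfo_channel"
  )
}

#' Construct an epoch from channels
#'
#' All channels of an epoch must span the same duration in seconds; sample
#' counts may differ when rates differ.
#'
#' @param ... `hfo_channel` objects (or a single list of them).
#' @param tol Relative tolerance for the equal-duration check.
#' @return An object of class `hfo_epoch`: a named list of channels plus a
#'   `duration_s` attribute.
#' @export
epoch <- function(..., tol = 1e-9) {
  chans <- list(...)
  if (length(chans) == 1L && !inherits(chans[[1L]], "hfo_channel")) {
    chans <- chans[[1L]]
  }
  if (length(chans) == 0L) stop("epoch needs at least one channel")
  for (ch in chans) {
    if (!inherits(ch, "hfo_channel")) stop("epoch(): all elements must be hfo_channel")
  }
  durs <- vapply(chans, function(ch) length(ch$samples) / ch$rate, numeric(1))
  if (max(durs) - min(durs) > tol * max(durs)) {
    stop("epoch(): channels span different durations (",
         paste(signif(durs, 10), collapse = ", "), " s)")
  }
  names(chans) <- vapply(chans, `[[`, character(1), "name")
  if (anyDuplicated(names(chans))) stop("epoch(): duplicate channel names")
  structure(chans, duration_s = durs[[1L]], class = "hfo_epoch")
}

#' Construct a recording
#'
#' A recording is an ordered collection of epochs (each a set of channels
#' covering one contiguous time span), with a subject identifier and an
#' optional start time.
#'
#' @param epochs A list of `hfo_epoch` objects (or a single epoch).
#' @param subject_id Subject identifier string.
#' @param start_time Optional `POSIXct` start time.
#' @return An object of class `hfo_recording`.
#' @export
recording <- function(epochs, subject_id = "anonymous", start_time = NULL) {
  if (inherits(epochs, "hfo_epoch")) epochs <- list(epochs)
  if (length(epochs) == 0L) stop("recording needs at least one epoch")
  for (ep in epochs) {
    if (!inherits(ep, "hfo_epoch")) stop("recording(): all elements must be hfo_epoch")
  }
  structure(
    list(epochs = epochs, subject_id = subject_id, start_time = start_time),
    class = "hfo_recording"
  )
}

#' @export
print.hfo_recording <- function(x, ...) {
  cat("<hfo_recording> subject:", x$subject_id,
      "| epochs:", length(x$epochs), "\n")
  for (i in seq_along(x$epochs)) {
    ep <- x$epochs[[i]]
    cat(sprintf("  epoch %d: %.6g s, %d channel(s): %s\n", i,
                epoch_duration(ep), length(ep),
                paste(names(ep), collapse = ", ")))
  }
  invisible(x)
}

#' Epoch duration in seconds
#' @param ep An `hfo_epoch`.
#' @return Duration in seconds.
#' @export
epoch_duration <- function(ep) attr(ep, "duration_s")

#' Number of epochs in a recording
#' @param rec An `hfo_recording`.
#' @return Integer epoch count.
#' @export
n_epochs <- function(rec) length(rec$epochs)

#' Fetch a channel from a recording
#' @param rec An `hfo_recording`.
#' @param name Channel name.
#' @param epoch_index 1-based epoch index.
#' @return The `hfo_channel`.
#' @export
get_channel <- function(rec, name, epoch_index = 1L) {
  ep <- rec$epochs[[epoch_index]]
  ch <- ep[[name]]
  if (is.null(ch)) stop("unknown channel '", name, "' in epoch ", epoch_index)
  ch
}

#' Apply a per-channel transform to every channel of a recording
#'
#' @param rec An `hfo_recording`.
#' @param fn Function `(samples, rate, name) -> samples` returning a vector of
#'   the same length.
#' @return A new `hfo_recording`; inputs are never modified.
#' @export
map_channels <- function(rec, fn) {
  eps <- lapply(rec$epochs, function(ep) {
    chans <- lapply(ep, function(ch) {
      out <- fn(ch$samples, ch$rate, ch$name)
      if (length(out) != length(ch$samples)) {
        stop("map_channels(): transform changed sample count on '", ch$name, "'")
      }
      channel(ch$name, ch$rate, out, ch$unit)
    })
    epoch(chans)
  })
  recording(eps, subject_id = rec$subject_id, start_time = rec$start_time)
}
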