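#' Construct an event list
#'
#' An event list is a data frame of time-bounded, labeled markers. Columns:
#' `epoch_index` (integer), `channel` (character), `onset` (seconds from
#' epoch start), `duration` (seconds, > 0), `label` (non-empty string; the
#' conventional labels are `"EOI"`, `"R"` ripple, `"F"` fast ripple, `"A"`
#' artifact), and optionally further per-event property columns (for example
#' `peak_freq`). Rows are kept sorted by (epoch_index, channel, onset).
#'
#' @param epoch_index Integer vector (1-based).
#' @param channel Character vector of channel names.
#' @param onset Numeric onsets in seconds, >= 0.
#' @param duration Numeric durations in seconds, > 0.
#' @param label Character labels.
#' @param ... Further equal-length property vectors, by name.
#' @return A `data.frame` of class `hfo_events`, sorted.
#' @export
event_list <- function(epoch_index = integer(), channel = character(),
                       onset = numeric(), duration = numeric(),
                       label = character(), ...) {
  df <- data.frame(
    epoch_index = as.integer(epoch_index),
    channel = as.character(channel),
    onset = as.numeric(onset),
    duration = as.numeric(duration),
    label = as.character(label),
    stringsAsFactors = FALSE
  )
  extra <- list(...)
  for (nm in names(extra)) df[[nm]] <- extra[[nm]]
  as_event_list(df)
}

#' Coerce a data frame to an event list
#'
#' Validates the marker invariants (positive duration, non-negative onset,
#' non-empty label) and sorts by (epoch_index, channel, onset).
#'
#' @param df A data frame with the `event_list()` columns.
#' @return An `hfo_events` data frame.
#' @export
as_event_list <- function(df) {
  need <- c("epoch_index", "channel", "onset", "duration", "label")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("event list missing column(s): ", paste(miss, collapse = ", "))
  if (nrow(df)) {
    if (any(df$duration <= 0)) stop("event list: zero or negative duration")
    if (any(df$onset < 0)) stop("event list: negative onset")
    if (any(!nzchar(df$label))) stop("event list: empty label")
    o <- order(df$epoch_index, df$channel, df$onset)
    df <- df[o, , drop = FALSE]
    rownames(df) <- NULL
  }
  class(df) <- c("hfo_events", "data.frame")
  df
}

#' Check markers against a recording's bounds
#'
#' @param events An `hfo_events` list.
#' @param rec The `hfo_recording` the markers refer to.
#' @return Invisibly `TRUE`; stops with the offending row otherwise.
#' @export
validate_events <- function(events, rec) {
  if (!nrow(events)) return(invisible(TRUE))
  for (i in seq_len(nrow(events))) {
    ei <- events$epoch_index[i]
    if (ei < 1L || ei > n_epochs(rec)) {
      stop("event row ", i, ": epoch_index ", ei, " out of range")
    }
    ep <- rec$epochs[[ei]]
    if (!events$channel[i] %in% names(ep)) {
      stop("event row ", i, ": unknown channel '", events$channel[i], "'")
    }
    dur <- epoch_duration(ep)
    if (events$onset[i] + events$duration[i] > dur + 1e-9) {
      stop("event row ", i, ": extends past epoch end (",
           events$onset[i] + events$duration[i], " > ", dur, " s)")
    }
  }
  invisible(TRUE)
}

#' Read / write marker tables
#'
#' CSV columns: `epoch_index, channel, onset_s, duration_s, label` plus any
#' property columns; the JSON form is an array of objects with the same keys.
#'
#' @param path File path; format chosen by extension (`.csv` or `.json`).
#' @param events An `hfo_events` list (for writing).
#' @return `read_markers()` returns an `hfo_events` list.
#' @export
read_markers <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    df <- jsonlite::fromJSON(path)
    if (length(df) == 0L) df <- data.frame()
  } else {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
  }
  if (!nrow(df)) return(event_list())
  names(df)[names(df) == "onset_s"] <- "onset"
  names(df)[names(df) == "duration_s"] <- "duration"
  as_event_list(df)
}

#' @rdname read_markers
#' @export
write_markers <- function(events, path) {
  df <- as.data.frame(events)
  names(df)[names(df) == "onset"] <- "onset_s"
  names(df)[names(df) == "duration"] <- "duration_s"
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(df, path, dataframe = "rows", digits = NA)
  } else {
    utils::write.csv(df, path, row.names = FALSE)
  }
  invisible(path)
}

#' Concatenate event lists
#' @param ... `hfo_events` objects.
#' @return A single sorted `hfo_events`.
#' @export
bind_events <- function(...) {
  parts <- Filter(function(x) nrow(x) > 0L, list(...))
  if (!length(parts)) return(event_list())
  cols <- Reduce(union, lapply(parts, names))
  parts <- lapply(parts, function(p) {
    for (nm in setdiff(cols, names(p))) p[[nm]] <- NA
    p[, cols, drop = FALSE]
  })
  as_event_list(do.call(rbind, lapply(parts, as.data.frame)))
}
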