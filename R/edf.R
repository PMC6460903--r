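# EDF/EDF+C container: 256-byte fixed header, 256 bytes per signal header,
# then data records of interleaved little-endian int16 samples. Annotations
# travel in an "EDF Annotations" signal as TALs
# ("+onset<0x15>duration<0x14>text<0x14><0x00>"). Only the continuous
# dialect (EDF+C) is supported; EDF+D is rejected.

edf_pad <- function(x, width) {
  x <- as.character(x)
  if (nchar(x, type = "bytes") > width) stop("EDF field too long: '", x, "'")
  sprintf("%-*s", width, x)
}

edf_num <- function(x, width) {
  s <- formatC(x, format = "fg", width = 1, flag = "")
  if (nchar(s) > width) s <- substr(formatC(x, digits = width, format = "g"), 1, width)
  edf_pad(s, width)
}

# Marker channel is encoded in the annotation text as "label@@channel"
# (EDF+ TALs carry no channel field); foreign files without the suffix get
# channel "".
edf_annot_text <- function(label, channel) paste0(label, "@@", channel)

edf_parse_annot_text <- function(txt) {
  parts <- strsplit(txt, "@@", fixed = TRUE)[[1L]]
  if (length(parts) >= 2L) list(label = parts[[1L]], channel = parts[[2L]])
  else list(label = txt, channel = "")
}

#' Write a recording to an EDF+C file
#'
#' Serializes a single-epoch recording plus its event markers as a
#' continuous EDF+ file with 16-bit samples and a TAL annotation signal.
#' Amplitudes outside the declared physical range raise an error rather
#' than being clipped. Multi-epoch recordings must be written one file per
#' epoch (see `segment_by_time()` to split them).
#'
#' @param rec Single-epoch `hfo_recording`.
#' @param path Output file path.
#' @param events Optional `hfo_events` to embed as annotations.
#' @param phys_min,phys_max Declared physical range per sample, in the
#'   channel unit. Default \eqn{\pm 3276.8} microvolt, i.e. a 0.1 uV
#'   quantization step at 16 bits.
#' @return `path`, invisibly.
#' @export
write_edf <- function(rec, path, events = NULL,
                      phys_min = -3276.8, phys_max = 3276.8) {
  if (n_epochs(rec) != 1L) {
    stop("write_edf(): one EDF file per epoch; got ", n_epochs(rec),
         " epochs (split the recording first)")
  }
  ep <- rec$epochs[[1L]]
  if (is.null(events)) events <- event_list()
  validate_events(events, rec)

  for (ch in ep) {
    if (min(ch$samples) < phys_min || max(ch$samples) > phys_max) {
      stop("write_edf(): channel '", ch$name, "' exceeds the physical range [",
           phys_min, ", ", phys_max, "]; no silent clipping")
    }
  }

  dur <- epoch_duration(ep)
  whole_seconds <- abs(dur - round(dur)) < 1e-9 &&
    all(vapply(ep, function(ch) abs(ch$rate - round(ch$rate)) < 1e-9, logical(1)))
  if (whole_seconds && round(dur) >= 1) {
    n_rec <- as.integer(round(dur))
    rec_dur <- 1
  } else {
    n_rec <- 1L
    rec_dur <- dur
  }
  spr <- vapply(ep, function(ch) {
    n <- ch$rate * rec_dur
    if (abs(n - round(n)) > 1e-6) {
      stop("write_edf(): channel '", ch$name,
           "' has a non-integer number of samples per record")
    }
    as.integer(round(n))
  }, integer(1))

  # TALs per record: a timekeeping TAL, plus every event whose onset falls in
  # the record. TALs are NUL-terminated, so they are assembled as raw bytes.
  nul <- as.raw(0L)
  tals <- vector("list", n_rec)
  for (r in seq_len(n_rec)) {
    t0 <- (r - 1L) * rec_dur
    parts <- list(charToRaw(
      sprintf("+%s\x14\x14", format(t0, trim = TRUE, scientific = FALSE))))
    if (nrow(events)) {
      sel <- which(events$onset >= t0 & events$onset < t0 + rec_dur |
                     (r == n_rec & events$onset >= t0))
      for (i in sel) {
        parts[[length(parts) + 1L]] <- charToRaw(sprintf(
          "+%s\x15%s\x14%s\x14",
          format(events$onset[i], trim = TRUE, scientific = FALSE),
          format(events$duration[i], trim = TRUE, scientific = FALSE),
          edf_annot_text(events$label[i], events$channel[i])))
      }
    }
    tals[[r]] <- unlist(lapply(parts, function(p) c(p, nul)))
  }
  annot_bytes <- max(vapply(tals, length, integer(1))) + 2L
  annot_spr <- as.integer(ceiling(annot_bytes / 2))

  ns <- length(ep) + 1L
  header_bytes <- 256L * (ns + 1L)
  st <- rec$start_time
  if (is.null(st)) st <- as.POSIXct("2000-01-01 00:00:00", tz = "UTC")

  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(s) writeBin(charToRaw(s), con)
  wr(edf_pad("0", 8))
  wr(edf_pad(paste("X X X", rec$subject_id), 80))
  wr(edf_pad("Startdate X X X X", 80))
  wr(edf_pad(format(st, "%d.%m.%y"), 8))
  wr(edf_pad(format(st, "%H.%M.%S"), 8))
  wr(edf_pad(header_bytes, 8))
  wr(edf_pad("EDF+C", 44))
  wr(edf_pad(n_rec, 8))
  wr(edf_num(rec_dur, 8))
  wr(edf_pad(ns, 4))

  labels <- c(vapply(ep, `[[`, character(1), "name"), "EDF Annotations")
  units <- c(vapply(ep, `[[`, character(1), "unit"), "")
  for (l in labels) wr(edf_pad(l, 16))
  for (l in labels) wr(edf_pad("", 80))                      # transducer
  for (u in units) wr(edf_pad(u, 8))
  for (i in seq_len(ns)) wr(edf_num(if (i < ns) phys_min else -1, 8))
  for (i in seq_len(ns)) wr(edf_num(if (i < ns) phys_max else 1, 8))
  for (i in seq_len(ns)) wr(edf_pad(-32768L, 8))
  for (i in seq_len(ns)) wr(edf_pad(32767L, 8))
  for (l in labels) wr(edf_pad("", 80))                      # prefilter
  for (n in c(spr, annot_spr)) wr(edf_pad(n, 8))
  for (l in labels) wr(edf_pad("", 32))

  scale <- 65535 / (phys_max - phys_min)
  for (r in seq_len(n_rec)) {
    for (k in seq_along(ep)) {
      x <- ep[[k]]$samples[((r - 1L) * spr[k] + 1L):(r * spr[k])]
      d <- as.integer(round((x - phys_min) * scale) - 32768)
      writeBin(d, con, size = 2L, endian = "little")
    }
    tal_raw <- tals[[r]]
    pad <- raw(annot_spr * 2L - length(tal_raw))
    writeBin(c(tal_raw, pad), con)
  }
  invisible(path)
}

edf_read_field <- function(raw, off, width) {
  trimws(rawToChar(raw[(off + 1L):(off + width)]))
}

#' Read an EDF/EDF+C file
#'
#' Parses the header, applies digital-to-physical scaling, converts TAL
#' annotations to event markers, and returns the signals as a single-epoch
#' recording. Discontinuous EDF+D files are rejected.
#'
#' @param path Path to an EDF/EDF+ file.
#' @return A list with elements `recording` (`hfo_recording`) and `events`
#'   (`hfo_events`).
#' @export
read_edf <- function(path) {
  if (!file.exists(path)) stop("read_edf(): no such file: ", path)
  sz <- file.info(path)$size
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "raw", 256L)
  if (length(hdr) < 256L) stop("read_edf(): truncated header")
  if (edf_read_field(hdr, 0L, 8L) != "0") {
    stop("read_edf(): malformed header (version field is not '0')")
  }
  patient <- edf_read_field(hdr, 8L, 80L)
  header_bytes <- as.integer(edf_read_field(hdr, 184L, 8L))
  reserved <- edf_read_field(hdr, 192L, 44L)
  if (startsWith(reserved, "EDF+D")) {
    stop("read_edf(): discontinuous EDF+D files are not supported")
  }
  n_rec <- as.integer(edf_read_field(hdr, 236L, 8L))
  if (is.na(n_rec) || n_rec <= 0L) {
    stop("read_edf(): header declares ", n_rec, " data records")
  }
  rec_dur <- as.numeric(edf_read_field(hdr, 244L, 8L))
  ns <- as.integer(edf_read_field(hdr, 252L, 4L))
  if (is.na(ns) || ns < 1L) stop("read_edf(): malformed signal count")

  shdr <- readBin(con, "raw", 256L * ns)
  fld <- function(block_off, width, i) {
    edf_read_field(shdr, block_off * ns + (i - 1L) * width, width)
  }
  labels <- vapply(seq_len(ns), function(i) fld(0L, 16L, i), character(1))
  units <- vapply(seq_len(ns), function(i) fld(96L, 8L, i), character(1))
  pmin <- as.numeric(vapply(seq_len(ns), function(i) fld(104L, 8L, i), character(1)))
  pmax <- as.numeric(vapply(seq_len(ns), function(i) fld(112L, 8L, i), character(1)))
  dmin <- as.numeric(vapply(seq_len(ns), function(i) fld(120L, 8L, i), character(1)))
  dmax <- as.numeric(vapply(seq_len(ns), function(i) fld(128L, 8L, i), character(1)))
  spr <- as.integer(vapply(seq_len(ns), function(i) fld(216L, 8L, i), character(1)))

  rec_bytes <- sum(spr) * 2L
  if (sz != header_bytes + as.double(rec_bytes) * n_rec) {
    stop("read_edf(): file size inconsistent with declared record size (",
         sz, " vs ", header_bytes + as.double(rec_bytes) * n_rec, " bytes)")
  }

  is_annot <- labels == "EDF Annotations"
  sig_idx <- which(!is_annot)
  data <- vector("list", ns)
  for (i in seq_len(ns)) data[[i]] <- vector("list", n_rec)
  for (r in seq_len(n_rec)) {
    for (i in seq_len(ns)) {
      if (is_annot[i]) {
        data[[i]][[r]] <- readBin(con, "raw", spr[i] * 2L)
      } else {
        data[[i]][[r]] <- readBin(con, "integer", spr[i], size = 2L,
                                  signed = TRUE, endian = "little")
      }
    }
  }

  chans <- lapply(sig_idx, function(i) {
    d <- unlist(data[[i]], use.names = FALSE)
    gain <- (pmax[i] - pmin[i]) / (dmax[i] - dmin[i])
    channel(labels[i], spr[i] / rec_dur, (d - dmin[i]) * gain + pmin[i], units[i])
  })
  subj <- patient
  m <- regmatches(patient, regexec("^X X X (.*)$", patient))[[1L]]
  if (length(m) == 2L) subj <- m[[2L]]
  rec <- recording(epoch(chans), subject_id = subj)

  events <- edf_collect_annotations(data, is_annot)
  list(recording = rec, events = events)
}

edf_collect_annotations <- function(data, is_annot) {
  rows <- list()
  for (i in which(is_annot)) {
    for (r in seq_along(data[[i]])) {
      raw_r <- data[[i]][[r]]
      # split the record's bytes into NUL-terminated TAL strings
      nz <- raw_r != as.raw(0L)
      grp <- cumsum(c(TRUE, diff(as.integer(nz)) == 1L))
      chunks <- vapply(split(raw_r[nz], grp[nz]), rawToChar, character(1))
      for (tal in chunks) {
        if (!nzchar(tal)) next
        fields <- strsplit(tal, "\x14", fixed = TRUE)[[1L]]
        if (length(fields) < 2L) next                 # timekeeping TAL
        onset_dur <- strsplit(fields[[1L]], "\x15", fixed = TRUE)[[1L]]
        onset <- as.numeric(onset_dur[[1L]])
        # instantaneous annotations (no duration field) get a 1 ms token
        # duration so the marker invariants (duration > 0) hold
        dur <- if (length(onset_dur) >= 2L) as.numeric(onset_dur[[2L]]) else 1e-3
        for (txt in fields[-1L]) {
          if (!nzchar(txt)) next
          parsed <- edf_parse_annot_text(txt)
          rows[[length(rows) + 1L]] <- data.frame(
            epoch_index = 1L, channel = parsed$channel, onset = onset,
            duration = dur, label = parsed$label, stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (!length(rows)) return(event_list())
  as_event_list(do.call(rbind, rows))
}
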