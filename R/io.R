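# Recording container and stream I/O: the in-memory dyad_recording class,
# a lossless single-file serialisation, and a reader/writer for XDF
# (eXtensible Data Format) multi-stream files with a unified clock.

#' Construct a dyad recording
#'
#' The central container: paired raw EEG (32 channels each), paired gaze
#' tracks, the event list, and metadata, all on one clock (seconds from
#' recording start).
#'
#' @param eeg_a,eeg_b Numeric matrices, 32 channels x samples (microvolts),
#'   row names = channel labels.
#' @param fs EEG sampling rate (Hz), identical for both participants.
#' @param labels Channel labels; must equal the montage set of
#'   [eeg_montage()].
#' @param gaze_a,gaze_b Gaze tracks: data frames `t` (s, sorted), `x`, `y`
#'   (px), `valid` (logical).
#' @param events Data frame with at least `time` (s, sorted) and `code`;
#'   canonical codes are `fixation_onset`, `stimulus_onset`, `ident`,
#'   `trial_end`, with `participant`, `cell`, `mode`, `run`, `trial`
#'   columns where applicable.
#' @param meta List of metadata (dyad id, gender composition, schedule, ...).
#' @return An object of class `dyad_recording`.
#' @export
dyad_recording <- function(eeg_a, eeg_b, fs, labels = eeg_montage(),
                           gaze_a, gaze_b, events, meta = list()) {
  if (nrow(eeg_a) != 32L || nrow(eeg_b) != 32L)
    stop("both EEG matrices must have 32 rows")
  if (!setequal(labels, eeg_montage()))
    stop("channel labels must equal the 32-channel montage")
  if (ncol(eeg_a) != ncol(eeg_b))
    stop("EEG matrices must have the same number of samples")
  if (is.unsorted(events$time)) stop("events must be sorted by time")
  for (g in list(gaze_a, gaze_b))
    if (nrow(g) && is.unsorted(g$t)) stop("gaze timestamps must be sorted")
  rownames(eeg_a) <- rownames(eeg_b) <- labels
  structure(list(eeg_a = eeg_a, eeg_b = eeg_b, fs = fs, labels = labels,
                 gaze_a = gaze_a, gaze_b = gaze_b, events = events,
                 meta = meta),
            class = "dyad_recording")
}

#' @export
print.dyad_recording <- function(x, ...) {
  dur <- ncol(x$eeg_a) / x$fs
  cat("<dyad_recording>", "\n")
  cat(sprintf("  EEG: 2 x 32 channels, %d samples @ %g Hz (%.1f s)\n",
              ncol(x$eeg_a), x$fs, dur))
  cat(sprintf("  gaze: %d / %d samples; events: %d (%d stimuli)\n",
              nrow(x$gaze_a), nrow(x$gaze_b), nrow(x$events),
              sum(x$events$code == "stimulus_onset")))
  if (!is.null(x$meta$dyad_id))
    cat(sprintf("  dyad %s (%s)\n", x$meta$dyad_id, x$meta$gender %||% "?"))
  invisible(x)
}

#' Write / read a recording losslessly
#'
#' Serialises a `dyad_recording` to a single self-describing binary file
#' and reads it back field-for-field. Reading a truncated or foreign file
#' raises an integrity error rather than returning partial data.
#'
#' @param rec A `dyad_recording`.
#' @param path File path.
#' @return `write_recording` returns `path` invisibly; `read_recording`
#'   returns the `dyad_recording`.
#' @export
write_recording <- function(rec, path) {
  stopifnot(inherits(rec, "dyad_recording"))
  saveRDS(list(format = "dyadsync-recording", version = 1L, payload = rec),
          path)
  invisible(path)
}

#' @rdname write_recording
#' @export
read_recording <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  obj <- tryCatch(readRDS(path), error = function(e)
    stop("integrity error reading ", path, ": ", conditionMessage(e)))
  if (!is.list(obj) || !identical(obj$format, "dyadsync-recording") ||
      !inherits(obj$payload, "dyad_recording"))
    stop("integrity error: ", path, " is not a dyad recording container")
  obj$payload
}

#' Export the event list as CSV
#'
#' @param rec A `dyad_recording`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
export_events_csv <- function(rec, path) {
  utils::write.csv(rec$events, path, row.names = FALSE)
  invisible(path)
}

## ---- XDF ------------------------------------------------------------------

xdf_write_varlen <- function(con, n) {
  if (n <= 255) {
    writeBin(as.raw(1L), con); writeBin(as.raw(n), con)
  } else {
    writeBin(as.raw(4L), con)
    writeBin(as.integer(n), con, size = 4L, endian = "little")
  }
}

xdf_chunk <- function(con, tag, content) {
  len <- length(content) + 2L
  xdf_write_varlen(con, len)
  writeBin(as.integer(tag), con, size = 2L, endian = "little")
  writeBin(content, con)
}

raw_uint32 <- function(x) writeBin(as.integer(x), raw(), size = 4L, endian = "little")
raw_double <- function(x) writeBin(as.numeric(x), raw(), size = 8L, endian = "little")

xdf_stream_header_xml <- function(name, type, channel_count, srate, format,
                                  channel_labels = NULL) {
  ch <- ""
  if (!is.null(channel_labels))
    ch <- paste0("<desc><channels>",
                 paste0("<channel><label>", channel_labels, "</label></channel>",
                        collapse = ""),
                 "</channels></desc>")
  sprintf(paste0("<?xml version=\"1.0\"?><info><name>%s</name><type>%s</type>",
                 "<channel_count>%d</channel_count><nominal_srate>%s</nominal_srate>",
                 "<channel_format>%s</channel_format>%s</info>"),
          name, type, channel_count, format(srate), format, ch)
}

xdf_samples_chunk_numeric <- function(stream_id, data, timestamps) {
  # data: channels x samples, written as double64, every sample stamped
  n <- ncol(data)
  body <- c(raw_uint32(stream_id),
            as.raw(4L), writeBin(as.integer(n), raw(), size = 4L, endian = "little"))
  interleaved <- rbind(timestamps, data)  # (1 + ch) x n
  payload <- writeBin(as.numeric(interleaved), raw(), size = 8L, endian = "little")
  # insert the per-sample 0x08 timestamp-length byte: rebuild sample-wise
  ch <- nrow(data)
  sample_bytes <- 8L * (1L + ch)
  m <- matrix(payload, nrow = sample_bytes)
  with_ts <- rbind(matrix(as.raw(8L), 1L, n), m)
  c(body, as.raw(with_ts))
}

xdf_samples_chunk_string <- function(stream_id, values, timestamps) {
  n <- length(values)
  body <- list(raw_uint32(stream_id), as.raw(4L),
               writeBin(as.integer(n), raw(), size = 4L, endian = "little"))
  for (i in seq_len(n)) {
    v <- charToRaw(values[i])
    body[[length(body) + 1L]] <- c(as.raw(8L), raw_double(timestamps[i]))
    if (length(v) <= 255) {
      body[[length(body) + 1L]] <- c(as.raw(1L), as.raw(length(v)))
    } else {
      body[[length(body) + 1L]] <- c(as.raw(4L),
        writeBin(length(v), raw(), size = 4L, endian = "little"))
    }
    body[[length(body) + 1L]] <- v
  }
  do.call(c, body)
}

#' Write a dyad recording as an XDF file
#'
#' Writes five streams (two 32-channel EEG, two 3-channel gaze, one string
#' marker stream) with per-sample timestamps on one unified clock, in the
#' standard XDF chunk layout. Event markers are encoded as
#' `code|participant|cell|mode|run|trial` strings.
#'
#' @param rec A `dyad_recording`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_xdf <- function(rec, path) {
  stopifnot(inherits(rec, "dyad_recording"))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw("XDF:"), con)
  xdf_chunk(con, 1L, charToRaw("<?xml version=\"1.0\"?><info><version>1.0</version></info>"))

  n <- ncol(rec$eeg_a)
  ts_eeg <- (seq_len(n) - 1) / rec$fs
  streams <- list(
    list(id = 1L, name = "EEG_A", type = "EEG", data = rec$eeg_a,
         srate = rec$fs, labels = rec$labels),
    list(id = 2L, name = "EEG_B", type = "EEG", data = rec$eeg_b,
         srate = rec$fs, labels = rec$labels)
  )
  for (s in streams) {
    xml <- xdf_stream_header_xml(s$name, s$type, 32L, s$srate, "double64", s$labels)
    xdf_chunk(con, 2L, c(raw_uint32(s$id), charToRaw(xml)))
  }
  gz <- list(list(id = 3L, name = "Gaze_A", g = rec$gaze_a),
             list(id = 4L, name = "Gaze_B", g = rec$gaze_b))
  for (s in gz) {
    xml <- xdf_stream_header_xml(s$name, "Gaze", 3L, 0, "double64",
                                 c("x", "y", "valid"))
    xdf_chunk(con, 2L, c(raw_uint32(s$id), charToRaw(xml)))
  }
  xml <- xdf_stream_header_xml("Markers", "Markers", 1L, 0, "string")
  xdf_chunk(con, 2L, c(raw_uint32(5L), charToRaw(xml)))

  # samples (chunked to keep memory bounded)
  step <- 20000L
  for (s in streams) {
    for (i0 in seq(1L, n, by = step)) {
      i1 <- min(n, i0 + step - 1L)
      xdf_chunk(con, 3L, xdf_samples_chunk_numeric(
        s$id, s$data[, i0:i1, drop = FALSE], ts_eeg[i0:i1]))
    }
  }
  for (s in gz) {
    g <- s$g
    if (nrow(g))
      xdf_chunk(con, 3L, xdf_samples_chunk_numeric(
        s$id, t(cbind(g$x, g$y, as.numeric(g$valid))), g$t))
  }
  ev <- rec$events
  if (nrow(ev)) {
    enc <- function(x) ifelse(is.na(x), "", as.character(x))
    strs <- paste(enc(ev$code), enc(ev$participant), enc(ev$cell),
                  enc(ev$mode), enc(ev$run), enc(ev$trial), sep = "|")
    xdf_chunk(con, 3L, xdf_samples_chunk_string(5L, strs, ev$time))
  }
  for (id in 1:5)
    xdf_chunk(con, 6L, c(raw_uint32(id),
                         charToRaw("<?xml version=\"1.0\"?><info></info>")))
  invisible(path)
}

xdf_read_varlen <- function(con) {
  nb <- readBin(con, "integer", 1L, size = 1L, signed = FALSE)
  if (length(nb) == 0L) return(NULL)
  if (nb == 1L) readBin(con, "integer", 1L, size = 1L, signed = FALSE)
  else if (nb == 4L) readBin(con, "integer", 1L, size = 4L, endian = "little")
  else if (nb == 8L) as.integer(readBin(con, "double", 1L, size = 8L, endian = "little"))
  else stop("malformed XDF varlen field")
}

parse_xdf_samples <- function(raw_body, stream) {
  con <- rawConnection(raw_body)
  on.exit(close(con))
  sid <- readBin(con, "integer", 1L, size = 4L, endian = "little")
  ns <- xdf_read_varlen(con)
  fmt <- stream$format
  ch <- stream$channel_count
  ts <- numeric(ns)
  last_ts <- stream$last_ts %||% 0
  dt <- if (stream$srate > 0) 1 / stream$srate else 0
  if (fmt == "string") {
    vals <- character(ns)
    for (i in seq_len(ns)) {
      tb <- readBin(con, "integer", 1L, size = 1L, signed = FALSE)
      ts[i] <- if (tb == 8L)
        readBin(con, "double", 1L, size = 8L, endian = "little")
      else last_ts + dt
      last_ts <- ts[i]
      len <- xdf_read_varlen(con)
      vals[i] <- rawToChar(readBin(con, "raw", len))
    }
    list(id = sid, ts = ts, values = vals, last_ts = last_ts)
  } else {
    size <- switch(fmt, float32 = 4L, double64 = 8L,
                   stop("unsupported XDF channel format: ", fmt))
    vals <- matrix(0, ch, ns)
    for (i in seq_len(ns)) {
      tb <- readBin(con, "integer", 1L, size = 1L, signed = FALSE)
      ts[i] <- if (tb == 8L)
        readBin(con, "double", 1L, size = 8L, endian = "little")
      else last_ts + dt
      last_ts <- ts[i]
      vals[, i] <- readBin(con, "double", ch, size = size, endian = "little")
    }
    list(id = sid, ts = ts, values = vals, last_ts = last_ts)
  }
}

read_xdf_streams <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- rawToChar(readBin(con, "raw", 4L))
  if (!identical(magic, "XDF:")) stop("not an XDF file: ", path)
  streams <- list()
  repeat {
    len <- xdf_read_varlen(con)
    if (is.null(len)) break
    tag <- readBin(con, "integer", 1L, size = 2L, endian = "little")
    body <- readBin(con, "raw", len - 2L)
    if (length(body) < len - 2L) stop("truncated XDF chunk")
    if (tag == 2L) {
      sid <- readBin(body[1:4], "integer", size = 4L, endian = "little")
      xml <- xml2::read_xml(rawToChar(body[-(1:4)]))
      txt <- function(q) xml2::xml_text(xml2::xml_find_first(xml, q))
      labels <- xml2::xml_text(xml2::xml_find_all(xml, ".//channels/channel/label"))
      streams[[as.character(sid)]] <- list(
        id = sid, name = txt("//name"), type = txt("//type"),
        channel_count = as.integer(txt("//channel_count")),
        srate = as.numeric(txt("//nominal_srate")),
        format = txt("//channel_format"),
        labels = if (length(labels)) labels else NULL,
        ts = list(), values = list(), last_ts = NULL)
    } else if (tag == 3L) {
      sid <- as.character(readBin(body[1:4], "integer", size = 4L,
                                  endian = "little"))
      st <- streams[[sid]]
      if (is.null(st)) stop("XDF samples for unknown stream ", sid)
      parsed <- parse_xdf_samples(body, st)
      st$ts[[length(st$ts) + 1L]] <- parsed$ts
      st$values[[length(st$values) + 1L]] <- parsed$values
      st$last_ts <- parsed$last_ts
      streams[[sid]] <- st
    }
    # tags 1 (file header), 4 (clock offset), 5 (boundary), 6 (footer):
    # nothing further needed for already-synchronised files
  }
  lapply(streams, function(st) {
    st$ts <- unlist(st$ts) %||% numeric(0)
    st$values <- if (st$format == "string") unlist(st$values) %||% character(0)
    else if (length(st$values)) do.call(cbind, st$values) else
      matrix(0, st$channel_count, 0L)
    st
  })
}

#' Read a dyad recording from an XDF file
#'
#' Parses the XDF chunk stream, resolves the five stream roles via
#' `stream_map`, aligns everything to a common clock (time zero at the
#' earliest sample of the mapped streams), resamples the two EEG streams
#' to a common rate (the lower of the two, recorded in `meta`) when they
#' differ, and decodes the marker strings into the canonical event table.
#'
#' @param path Path to an `.xdf` file.
#' @param stream_map Named character vector mapping roles
#'   `c("eeg_a", "eeg_b", "gaze_a", "gaze_b", "markers")` to stream names
#'   in the file.
#' @param marker_parse Function turning the character vector of marker
#'   strings into the canonical event columns; the default decodes the
#'   `code|participant|cell|mode|run|trial` vocabulary of [write_xdf()].
#'   Supply a custom translator for deposits with a different vocabulary.
#' @return A `dyad_recording`.
#' @export
read_xdf <- function(path,
                     stream_map = c(eeg_a = "EEG_A", eeg_b = "EEG_B",
                                    gaze_a = "Gaze_A", gaze_b = "Gaze_B",
                                    markers = "Markers"),
                     marker_parse = parse_marker_strings) {
  if (!file.exists(path)) stop("no such file: ", path)
  roles <- c("eeg_a", "eeg_b", "gaze_a", "gaze_b", "markers")
  missing_roles <- setdiff(roles, names(stream_map))
  if (length(missing_roles))
    stop("stream_map is missing role(s): ", paste(missing_roles, collapse = ", "))
  streams <- read_xdf_streams(path)
  by_name <- stats::setNames(streams, vapply(streams, `[[`, "", "name"))
  pick <- function(role) {
    nm <- stream_map[[role]]
    st <- by_name[[nm]]
    if (is.null(st))
      stop("stream for role \"", role, "\" (named \"", nm, "\") not found in ", path)
    st
  }
  ea <- pick("eeg_a"); eb <- pick("eeg_b")
  ga <- pick("gaze_a"); gb <- pick("gaze_b")
  mk <- pick("markers")

  t0 <- min(c(if (length(ea$ts)) ea$ts[1] else Inf,
              if (length(eb$ts)) eb$ts[1] else Inf,
              if (length(ga$ts)) ga$ts[1] else Inf,
              if (length(gb$ts)) gb$ts[1] else Inf,
              if (length(mk$ts)) mk$ts[1] else Inf))
  if (!is.finite(t0)) stop("XDF file contains no samples")

  meta <- list(source = path)
  fs <- min(ea$srate, eb$srate)
  if (ea$srate != eb$srate) {
    meta$resampled_from <- c(eeg_a = ea$srate, eeg_b = eb$srate)
    if (ea$srate > fs) ea$values <- resample_to(ea$values, ea$srate, fs)
    if (eb$srate > fs) eb$values <- resample_to(eb$values, eb$srate, fs)
  }
  for (st in list(ea, eb, ga, gb, mk))
    if (length(st$ts) > 1L && is.unsorted(st$ts))
      stop("non-monotone timestamps in stream ", st$name)

  gaze_df <- function(st) {
    if (!length(st$ts))
      return(data.frame(t = numeric(0), x = numeric(0), y = numeric(0),
                        valid = logical(0)))
    data.frame(t = st$ts - t0, x = st$values[1, ], y = st$values[2, ],
               valid = st$values[3, ] > 0.5)
  }
  events <- marker_parse(mk$values)
  events$time <- mk$ts - t0
  events <- events[order(events$time, method = "radix"),
                   c("time", setdiff(names(events), "time"))]
  rownames(events) <- NULL

  labels <- ea$labels %||% eeg_montage()
  eeg_a <- ea$values; eeg_b <- eb$values
  rownames(eeg_a) <- labels
  rownames(eeg_b) <- eb$labels %||% labels
  dyad_recording(eeg_a = eeg_a, eeg_b = eeg_b, fs = fs, labels = labels,
                 gaze_a = gaze_df(ga), gaze_b = gaze_df(gb),
                 events = events, meta = meta)
}

#' Decode canonical marker strings
#'
#' @param strs Character vector of `code|participant|cell|mode|run|trial`
#'   marker strings.
#' @return Data frame of event columns (without `time`).
#' @export
parse_marker_strings <- function(strs) {
  parts <- strsplit(strs, "|", fixed = TRUE)
  field <- function(i) vapply(parts, function(p) if (length(p) >= i) p[i] else "", "")
  num_or_na <- function(x) suppressWarnings(as.integer(ifelse(x == "", NA, x)))
  chr_or_na <- function(x) ifelse(x == "", NA_character_, x)
  data.frame(
    time = NA_real_,
    code = field(1),
    participant = chr_or_na(field(2)),
    cell = num_or_na(field(3)),
    mode = chr_or_na(field(4)),
    run = num_or_na(field(5)),
    trial = num_or_na(field(6)),
    stringsAsFactors = FALSE
  )
}
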