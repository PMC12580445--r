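# Readers/writers: EDF (the format sleep studies distribute), CSV, and
# NSRR-style annotation XML.  No EDF package exists in this stack, so a
# minimal continuous 16-bit EDF reader/writer is implemented here.

pad_field <- function(x, width) {
  x <- substr(as.character(x), 1L, width)
  formatC(x, width = -width, flag = "-")
}

# shortest "g" representation that fits an 8-char EDF numeric field
fmt_num8 <- function(x) {
  for (d in 7:1) {
    s <- formatC(x, format = "g", digits = d)
    if (nchar(s) <= 8) return(s)
  }
  stop("cannot represent ", x, " in an 8-character EDF field", call. = FALSE)
}

#' Write a single-channel EDF file
#'
#' Minimal continuous EDF writer: one signal, 1-second data records,
#' 16-bit samples scaled linearly between the signal's physical range and
#' the full digital range.  The sampling rate must therefore be a whole
#' number of samples per second.  The final partial record is padded by
#' repeating the last sample.
#'
#' @param signal Numeric signal.
#' @param fs Sampling rate in Hz (positive integer).
#' @param path Output file path.
#' @param label Channel label (<= 16 characters), default `"AIRFLOW"`.
#' @param physical_dim Physical dimension string (default `"au"`,
#'   arbitrary units, as appropriate for thermistor airflow).
#' @return `path`, invisibly.
#' @seealso [read_edf()]
#' @export
write_edf <- function(signal, fs, path, label = "AIRFLOW",
                      physical_dim = "au") {
  stopifnot(is.numeric(signal), length(signal) > 0)
  if (fs <= 0 || fs != round(fs)) {
    stop("EDF writer requires a positive integer sampling rate", call. = FALSE)
  }
  fs <- as.integer(fs)
  n_rec <- ceiling(length(signal) / fs)
  pad <- n_rec * fs - length(signal)
  if (pad > 0) signal <- c(signal, rep(signal[length(signal)], pad))

  pmin_ <- min(signal)
  pmax_ <- max(signal)
  if (pmax_ <= pmin_) pmax_ <- pmin_ + 1
  dmin <- -32768L
  dmax <- 32767L
  dig <- as.integer(round((signal - pmin_) / (pmax_ - pmin_) *
                            (dmax - dmin) + dmin))

  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    pad_field("0", 8), pad_field("X", 80), pad_field("X", 80),
    pad_field("01.01.00", 8), pad_field("00.00.00", 8),
    pad_field(256L * 2L, 8), pad_field("", 44),
    pad_field(n_rec, 8), pad_field("1", 8), pad_field("1", 4),
    pad_field(label, 16), pad_field("", 80), pad_field(physical_dim, 8),
    pad_field(fmt_num8(pmin_), 8), pad_field(fmt_num8(pmax_), 8),
    pad_field(dmin, 8), pad_field(dmax, 8), pad_field("", 80),
    pad_field(fs, 8), pad_field("", 32))
  writeChar(hdr, con, eos = NULL)
  writeBin(dig, con, size = 2L, endian = "little")
  invisible(path)
}

#' Read a channel from an EDF file
#'
#' Minimal reader for continuous 16-bit EDF: parses the header, picks the
#' requested channel by case-insensitive label match, and rescales digital
#' samples to physical units.
#'
#' @param path EDF file path.
#' @param channel Channel label (case-insensitive).  `NULL` (default)
#'   takes the first channel.
#' @return List with `signal` (numeric), `fs` (Hz), `label`, and
#'   `channels` (all labels present).
#' @export
read_edf <- function(path, channel = NULL) {
  if (!file.exists(path)) {
    stop("file not found: ", path, call. = FALSE)
  }
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(width) trimws(readChar(con, width, useBytes = TRUE))
  rd(8); rd(80); rd(80); rd(8); rd(8)
  rd(8)                                  # header bytes (recomputed below)
  rd(44)
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  labels <- vapply(seq_len(ns), function(i) rd(16), character(1))
  for (i in seq_len(ns)) rd(80)          # transducer
  for (i in seq_len(ns)) rd(8)           # physical dimension
  pmin_ <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), numeric(1))
  pmax_ <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), numeric(1))
  dmin <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), numeric(1))
  dmax <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), numeric(1))
  for (i in seq_len(ns)) rd(80)          # prefiltering
  nsamp <- vapply(seq_len(ns), function(i) as.integer(rd(8)), integer(1))
  for (i in seq_len(ns)) rd(32)          # reserved

  idx <- if (is.null(channel)) 1L else {
    m <- which(tolower(labels) == tolower(channel))
    if (length(m) == 0L) {
      stop("channel '", channel, "' not found; available channels: ",
           paste(labels, collapse = ", "), call. = FALSE)
    }
    m[1L]
  }
  per_rec <- sum(nsamp)
  raw <- readBin(con, "integer", n = n_rec * per_rec, size = 2L,
                 signed = TRUE, endian = "little")
  offs <- c(0L, cumsum(nsamp))
  sel <- as.vector(outer(offs[idx] + seq_len(nsamp[idx]),
                         (seq_len(n_rec) - 1L) * per_rec, `+`))
  dig <- raw[sel]
  sig <- (dig - dmin[idx]) / (dmax[idx] - dmin[idx]) *
    (pmax_[idx] - pmin_[idx]) + pmin_[idx]
  list(signal = sig, fs = nsamp[idx] / rec_dur, label = labels[idx],
       channels = labels)
}

#' Write an airflow signal as CSV
#'
#' Two columns, `time_s` and `flow`, at full precision.
#'
#' @param signal Numeric signal.
#' @param fs Sampling rate in Hz.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_airflow_csv <- function(signal, fs, path) {
  df <- data.frame(time_s = (seq_along(signal) - 1) / fs, flow = signal)
  utils::write.csv(format(df, digits = 15, trim = TRUE, scientific = FALSE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an airflow signal from EDF or CSV
#'
#' Dispatches on the file extension: `.edf` files go through [read_edf()]
#' (with case-insensitive channel matching); anything else is read as CSV
#' with columns `time_s` and `flow`, the sampling rate inferred from the
#' median time step.
#'
#' @param path File path.
#' @param channel EDF channel label (ignored for CSV).
#' @return List with `signal` and `fs`.
#' @export
read_airflow <- function(path, channel = NULL) {
  if (!file.exists(path)) {
    stop("file not found: ", path, call. = FALSE)
  }
  if (grepl("\\.edf$", path, ignore.case = TRUE)) {
    edf <- read_edf(path, channel)
    return(list(signal = edf$signal, fs = edf$fs))
  }
  df <- utils::read.csv(path)
  stopifnot(all(c("time_s", "flow") %in% names(df)))
  fs <- 1 / stats::median(diff(df$time_s))
  list(signal = df$flow, fs = fs)
}

#' Write respiratory events as CSV
#'
#' @param events Data frame with `onset_s`, `duration_s`, `type`, `stage`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_events_csv <- function(events, path) {
  utils::write.csv(events[, c("onset_s", "duration_s", "type", "stage")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write respiratory events as NSRR-style annotation XML
#'
#' Emits `<ScoredEvent>` elements with `EventConcept`, `Start`, `Duration`
#' and `SleepStage` children under `<PSGAnnotation><ScoredEvents>`.
#'
#' @param events Data frame with `onset_s`, `duration_s`, `type`, `stage`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_events_xml <- function(events, path) {
  doc <- xml2::xml_new_root("PSGAnnotation")
  se <- xml2::xml_add_child(doc, "ScoredEvents")
  for (i in seq_len(nrow(events))) {
    ev <- xml2::xml_add_child(se, "ScoredEvent")
    concept <- if (events$type[i] == "apnea") {
      "Obstructive apnea|Obstructive Apnea"
    } else {
      "Hypopnea|Hypopnea"
    }
    xml2::xml_add_child(ev, "EventType", "Respiratory|Respiratory")
    xml2::xml_add_child(ev, "EventConcept", concept)
    xml2::xml_add_child(ev, "Start", format(events$onset_s[i], digits = 12))
    xml2::xml_add_child(ev, "Duration",
                        format(events$duration_s[i], digits = 12))
    xml2::xml_add_child(ev, "SleepStage", events$stage[i])
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

#' Read respiratory events from CSV or NSRR-style XML
#'
#' CSV files need columns `onset_s`, `duration_s`, `type`, `stage`.  XML
#' files are scanned for `ScoredEvent` elements whose `EventConcept` (or
#' `Name`) mentions apnea or hypopnea; other scored events are ignored.
#' Events are sorted by onset.  Durations of 10 s or less draw a warning
#' but are retained (the annotation file is the scoring authority);
#' overlapping events are an error reporting the offending indices.
#'
#' @param path File path (`.xml` for annotation XML, anything else CSV).
#' @return Data frame with `onset_s`, `duration_s`, `type`, `stage`,
#'   sorted by onset.
#' @export
read_events <- function(path) {
  if (!file.exists(path)) {
    stop("file not found: ", path, call. = FALSE)
  }
  if (grepl("\\.xml$", path, ignore.case = TRUE)) {
    doc <- xml2::read_xml(path)
    nodes <- xml2::xml_find_all(doc, ".//ScoredEvent")
    rows <- lapply(nodes, function(nd) {
      name <- xml2::xml_text(xml2::xml_find_first(nd, "./EventConcept"))
      if (is.na(name)) {
        name <- xml2::xml_text(xml2::xml_find_first(nd, "./Name"))
      }
      if (is.na(name) || !grepl("apnea|hypopnea", name, ignore.case = TRUE)) {
        return(NULL)
      }
      stage <- xml2::xml_text(xml2::xml_find_first(nd, "./SleepStage"))
      data.frame(
        onset_s = as.numeric(xml2::xml_text(xml2::xml_find_first(nd, "./Start"))),
        duration_s = as.numeric(xml2::xml_text(xml2::xml_find_first(nd, "./Duration"))),
        type = if (grepl("hypopnea", name, ignore.case = TRUE)) "hypopnea" else "apnea",
        stage = if (is.na(stage)) "NREM" else stage,
        stringsAsFactors = FALSE)
    })
    rows <- rows[!vapply(rows, is.null, logical(1))]
    ev <- if (length(rows)) do.call(rbind, rows) else
      data.frame(onset_s = numeric(), duration_s = numeric(),
                 type = character(), stage = character(),
                 stringsAsFactors = FALSE)
  } else {
    ev <- utils::read.csv(path, stringsAsFactors = FALSE)
    stopifnot(all(c("onset_s", "duration_s", "type", "stage") %in% names(ev)))
  }
  validate_events(ev)
}

validate_events <- function(ev) {
  ev <- ev[order(ev$onset_s), , drop = FALSE]
  rownames(ev) <- NULL
  if (nrow(ev) > 1) {
    ends <- ev$onset_s + ev$duration_s
    bad <- which(ev$onset_s[-1L] < ends[-nrow(ev)])
    if (length(bad)) {
      stop("overlapping events at indices: ",
           paste(bad, bad + 1L, sep = "-", collapse = ", "), call. = FALSE)
    }
  }
  short <- which(ev$duration_s <= 10)
  if (length(short)) {
    warning(length(short), " event(s) with duration <= 10 s retained ",
            "(annotations are authoritative)")
  }
  ev
}
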