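#' Construct a PEDB series
#'
#' A PEDB series holds one post-event deep breathing value per retained
#' respiratory event, in temporal order: the mean peak-to-peak amplitude of
#' the first (up to three) breaths after each event.  The first and last
#' entries correspond to the participant's first and last respiratory
#' events of the night.
#'
#' @param values Nonnegative PEDB values (flow units).
#' @param onset_s,duration_s Event onsets (strictly increasing) and
#'   durations in seconds.
#' @param stage Per-event sleep stage label (`"REM"`/`"NREM"`).
#' @param n_breaths_used Breaths averaged per event (1-3).
#' @param participant_id Identifier carried through the pipeline.
#' @param stage_filter Which stage subset this series represents
#'   (`"TST"`, `"NREM"` or `"REM"`).
#' @param n_dropped Number of events dropped for lack of post-event breaths.
#' @return Object of class `pedb_series`: a data frame with columns
#'   `event_index`, `onset_s`, `duration_s`, `stage`, `n_breaths_used`,
#'   `pedb`, plus attributes `participant_id`, `stage_filter`, `n_dropped`.
#' @export
pedb_series <- function(values, onset_s, duration_s, stage,
                        n_breaths_used = rep(3L, length(values)),
                        participant_id = "unknown", stage_filter = "TST",
                        n_dropped = 0L) {
  n <- length(values)
  stopifnot(length(onset_s) == n, length(duration_s) == n,
            length(stage) == n, length(n_breaths_used) == n)
  if (n > 0) {
    stopifnot(all(values >= 0), all(diff(onset_s) > 0),
              all(n_breaths_used %in% 1:3))
  }
  out <- data.frame(event_index = seq_len(n), onset_s = onset_s,
                    duration_s = duration_s, stage = stage,
                    n_breaths_used = as.integer(n_breaths_used),
                    pedb = values, stringsAsFactors = FALSE)
  attr(out, "participant_id") <- participant_id
  attr(out, "stage_filter") <- stage_filter
  attr(out, "n_dropped") <- n_dropped
  class(out) <- c("pedb_series", "data.frame")
  out
}

#' @export
print.pedb_series <- function(x, ...) {
  cat(sprintf("<pedb_series> participant %s, stage %s: %d events",
              attr(x, "participant_id"), attr(x, "stage_filter"), nrow(x)))
  if (attr(x, "n_dropped") > 0) {
    cat(sprintf(" (%d dropped: no post-event breaths)", attr(x, "n_dropped")))
  }
  cat("\n")
  if (nrow(x) > 0) {
    cat(sprintf("  PEDB range %.3g-%.3g over %.2f h\n", min(x$pedb),
                max(x$pedb), (max(x$onset_s) - min(x$onset_s)) / 3600))
  }
  invisible(x)
}

#' Segment an airflow signal into breaths
#'
#' Breaths are delimited by successive inspiratory onsets: upward zero
#' crossings of a low-pass-smoothed, mean-detrended copy of the signal.
#' Peak-to-peak amplitudes are always measured on the raw signal within
#' each segment, so detection smoothing never biases amplitudes.  Segments
#' shorter than `min_breath_s` or with peak-to-peak amplitude below
#' `min_p2p_frac` of the window's median are rejected as noise crossings.
#'
#' @param airflow Numeric airflow signal.
#' @param fs Sampling rate in Hz (> 0).
#' @param window Optional `c(start_s, end_s)` restricting detection to a
#'   sub-interval (half-open, seconds from recording start).
#' @param smooth_cutoff_hz Low-pass cutoff for the detection copy
#'   (default 1 Hz, comfortably above resting breathing rates).
#' @param min_breath_s Minimum breath duration in seconds (default 1).
#' @param min_p2p_frac Minimum peak-to-peak amplitude as a fraction of the
#'   window's median breath amplitude (default 0.01).
#' @return Data frame with columns `start_s`, `end_s`, `p2p`, ordered and
#'   non-overlapping.  Empty (zero-row) when no breath is found.
#' @examples
#' fs <- 100
#' t <- seq(0, 60 - 1 / fs, by = 1 / fs)
#' x <- sin(2 * pi * 0.25 * t)
#' nrow(detect_breaths(x, fs))  # 15 breaths in 60 s at 0.25 Hz
#' @export
detect_breaths <- function(airflow, fs, window = NULL,
                           smooth_cutoff_hz = 1, min_breath_s = 1,
                           min_p2p_frac = 0.01) {
  stopifnot(is.numeric(airflow), fs > 0)
  offset_s <- 0
  if (!is.null(window)) {
    stopifnot(length(window) == 2, window[2] > window[1])
    i0 <- max(1L, floor(window[1] * fs) + 1L)
    i1 <- min(length(airflow), ceiling(window[2] * fs))
    if (i1 <= i0) return(empty_breaths())
    airflow <- airflow[i0:i1]
    offset_s <- (i0 - 1L) / fs
  }
  n <- length(airflow)
  if (n < 4L) return(empty_breaths())

  sm <- airflow
  # filtfilt needs a few filter lengths of signal; skip smoothing for stubs.
  # Odd reflection padding suppresses the filter's edge transients so that
  # breaths at the very start/end of the window are still delimited.
  if (n > 24L) {
    w <- min(smooth_cutoff_hz / (fs / 2), 0.99)
    bf <- signal::butter(2, w)
    np <- min(n - 1L, ceiling(3 * fs / smooth_cutoff_hz))
    padded <- c(2 * airflow[1] - airflow[(np + 1L):2L], airflow,
                2 * airflow[n] - airflow[(n - 1L):(n - np)])
    sm <- signal::filtfilt(bf, padded)[(np + 1L):(np + n)]
  }
  sm <- sm - mean(sm)
  if (diff(range(sm)) <= 1e-12 * max(1, max(abs(airflow)))) {
    return(empty_breaths())                      # flat signal, no breaths
  }

  up <- which(sm[-n] <= 0 & sm[-1L] > 0)
  # the window may open exactly at an inspiratory onset: count it as one
  if (!1L %in% up && abs(sm[1]) <= 0.02 * max(abs(sm)) && sm[2] >= sm[1]) {
    up <- c(1L, up)
  }
  if (length(up) == 0L) return(empty_breaths())
  starts <- up
  ends <- c(up[-1L], n + 1L)                     # half-open [start, end)
  p2p <- vapply(seq_along(starts), function(k) {
    seg <- airflow[starts[k]:(ends[k] - 1L)]
    max(seg) - min(seg)
  }, numeric(1))

  keep <- (ends - starts) / fs >= min_breath_s & p2p > 0
  if (any(keep)) {
    keep <- keep & p2p >= min_p2p_frac * stats::median(p2p[keep])
  }
  data.frame(start_s = offset_s + (starts[keep] - 1L) / fs,
             end_s = offset_s + (ends[keep] - 1L) / fs,
             p2p = p2p[keep])
}

empty_breaths <- function() {
  data.frame(start_s = numeric(), end_s = numeric(), p2p = numeric())
}

#' Select the post-event deep-breath triplet for one event
#'
#' Returns the first up-to-three breaths that start at or after the event
#' offset (onset + duration) and end before the next event's onset.  When
#' fewer than three such breaths exist, the available 1-2 are returned;
#' when none exist, `NULL`.
#'
#' @param breaths Breath table from [detect_breaths()], ordered by start.
#' @param event A list or one-row data frame with `onset_s` and
#'   `duration_s`.
#' @param next_onset_s Onset of the following event in seconds, or `Inf`
#'   (the default) when there is none.
#' @param tol_s Boundary tolerance in seconds (default 0.5): detection
#'   smoothing can shift a breath onset slightly across the annotated
#'   event offset, so a breath starting within `tol_s` before the offset
#'   still counts as post-event.
#' @return A list with `amplitudes` (numeric, length 1-3) and
#'   `n_breaths_used`, or `NULL` when no post-event breath exists.
#' @export
post_event_breaths <- function(breaths, event, next_onset_s = Inf,
                               tol_s = 0.5) {
  stopifnot(is.data.frame(breaths))
  off <- event$onset_s + event$duration_s
  sel <- which(breaths$start_s >= off - tol_s &
                 breaths$end_s <= next_onset_s + tol_s)
  if (length(sel) == 0L) return(NULL)
  sel <- sel[seq_len(min(3L, length(sel)))]
  list(amplitudes = breaths$p2p[sel], n_breaths_used = length(sel))
}

#' PEDB value of one post-event breath triplet
#'
#' The arithmetic mean of the available post-event peak-to-peak amplitudes
#' (three when the full triplet exists; the 1/3 factor generalizes to 1/n
#' for truncated triplets).
#'
#' @param triplet A triplet from [post_event_breaths()] (must not be
#'   `NULL`).
#' @return A single nonnegative PEDB value in flow units.
#' @examples
#' compute_pedb(list(amplitudes = c(3, 2, 1), n_breaths_used = 3))  # 2
#' @export
compute_pedb <- function(triplet) {
  if (is.null(triplet) || triplet$n_breaths_used < 1L) {
    stop("triplet must contain at least one post-event breath", call. = FALSE)
  }
  mean(triplet$amplitudes)
}

#' Extract the PEDB series of one participant
#'
#' Segments the whole airflow signal into breaths, then computes one PEDB
#' value per respiratory event: the mean peak-to-peak amplitude of the
#' first up-to-three breaths between that event's offset and the next
#' event's onset.  Events with zero recoverable post-event breaths are
#' dropped (and counted in the result's `n_dropped` attribute).  Triplet
#' selection always uses the full event list; the stage filter is applied
#' afterwards, so NREM and REM series partition the TST series.
#'
#' @param airflow Numeric airflow signal.
#' @param fs Sampling rate in Hz.
#' @param events Data frame of respiratory events (`onset_s`,
#'   `duration_s`, `type`, `stage`), sorted and non-overlapping.
#' @param stage_filter `"TST"` (all events, default), `"NREM"` or `"REM"`.
#' @param participant_id Identifier stored on the series.
#' @param normalize If `TRUE`, divide PEDB values by the participant's
#'   median breath amplitude (an option for uncalibrated thermistor
#'   signals; default `FALSE`, raw peak-to-peak units).
#' @param ... Passed to [detect_breaths()].
#' @return A [pedb_series()]; zero-row when no event is retained.
#' @export
build_pedb_series <- function(airflow, fs, events, stage_filter = "TST",
                              participant_id = "unknown",
                              normalize = FALSE, ...) {
  stage_filter <- match.arg(stage_filter, c("TST", "NREM", "REM"))
  stopifnot(is.data.frame(events))
  if (nrow(events) > 1 && any(diff(events$onset_s) <= 0)) {
    stop("events must be sorted by onset", call. = FALSE)
  }
  if (nrow(events) > 1 &&
      any(events$onset_s[-1L] <
          events$onset_s[-nrow(events)] + events$duration_s[-nrow(events)])) {
    stop("events must not overlap", call. = FALSE)
  }
  breaths <- detect_breaths(airflow, fs, ...)
  n_ev <- nrow(events)
  vals <- rep(NA_real_, n_ev)
  nb <- integer(n_ev)
  for (i in seq_len(n_ev)) {
    nxt <- if (i < n_ev) events$onset_s[i + 1L] else Inf
    tri <- post_event_breaths(breaths, events[i, ], next_onset_s = nxt)
    if (!is.null(tri)) {
      vals[i] <- compute_pedb(tri)
      nb[i] <- tri$n_breaths_used
    }
  }
  keep <- !is.na(vals)
  if (stage_filter != "TST") keep <- keep & events$stage == stage_filter
  scale <- 1
  if (normalize && nrow(breaths) > 0) scale <- stats::median(breaths$p2p)
  pedb_series(values = vals[keep] / scale,
              onset_s = events$onset_s[keep],
              duration_s = events$duration_s[keep],
              stage = events$stage[keep],
              n_breaths_used = nb[keep],
              participant_id = participant_id,
              stage_filter = stage_filter,
              n_dropped = sum(is.na(vals)))
}

#' Extract the PEDB series directly from a synthetic record
#'
#' Convenience wrapper running [build_pedb_series()] on a `psg_record`'s
#' airflow and annotations.
#'
#' @param record A `psg_record` from [simulate_record()] (with airflow).
#' @inheritParams build_pedb_series
#' @return A [pedb_series()].
#' @export
extract_record <- function(record, stage_filter = "TST",
                           participant_id = "unknown", ...) {
  stopifnot(inherits(record, "psg_record"))
  if (is.null(record$airflow)) {
    stop("record has no airflow signal (simulated with signal = FALSE); ",
         "use truth_pedb_series() instead", call. = FALSE)
  }
  build_pedb_series(record$airflow, record$fs, record$events,
                    stage_filter = stage_filter,
                    participant_id = participant_id, ...)
}
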