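#' Forward-validation window labeling
#'
#' Labels an analysis block into true/false positive/negative prediction
#' windows by a single forward scan, the event-based scheme used to
#' validate continuous hypotension alarms:
#'
#' \itemize{
#'   \item An alert is \emph{active} at a scan position when the position
#'     lies inside a maximal run of at least 3 consecutive samples with
#'     index strictly above the threshold; the alert anchor is the later
#'     of the run start and the scan position, so an exceedance still in
#'     progress after a labeled window re-alerts immediately. Anchors
#'     falling inside an ongoing hypotensive event do not open windows
#'     (the event is under way, not predicted).
#'   \item At the earliest alert anchor within `window` seconds of the
#'     scan position, a window of `window` seconds opens at the anchor.
#'     If a hypotensive event onset falls inside it the window is TP with
#'     `time_to_event = onset - anchor`, and scanning resumes at the
#'     event end (first sample with MAP back at/above 65 mmHg);
#'     otherwise FP, resuming at the window end.
#'   \item If neither an alert anchor nor an event onset occurs within
#'     `window` seconds of the scan position, that span is one negative
#'     prediction: FN if an event onset falls inside it (the event was
#'     unpredicted; resume at its end), else TN (resume at the span
#'     end). Negative spans advance in fixed jumps so the absence of
#'     hypotension is counted once per window.
#'   \item A trailing partial span containing neither alert nor event is
#'     discarded.
#' }
#'
#' Each event onset therefore contributes to exactly one label (TP or
#' FN), and no two windows overlap.
#'
#' @param rec a censored [recording()].
#' @param block one analysis block (see [detect_hypotension()]).
#' @param threshold alert threshold in index units, `[0, 100]`.
#' @param window prediction window length in seconds; a positive
#'   multiple of 20 (default 1200 = 20 min).
#' @param map_threshold hypotension threshold, mmHg.
#' @return A data frame of class `hypoval_labels`, one row per labeled
#'   window: `window_start` (sample index), `label` (factor TP/TN/FP/FN),
#'   `alert_sample`, `event_onset_sample` (NA when absent) and
#'   `time_to_event_s`.
#' @examples
#' # a 3-sample alert predicting an event 180 s after the alert start
#' map <- rep(75, 120); map[10:12] <- 60
#' idx <- rep(0, 120); idx[1:3] <- 90
#' rec <- recording(map = map, index = idx)
#' forward_validate(rec, c(1, 121), threshold = 85)
#' @export
forward_validate <- function(rec, block, threshold, window = 1200,
                             map_threshold = 65) {
  stopifnot(inherits(rec, "hypoval_recording"))
  if (window <= 0 || abs(window %% GRID_PERIOD_S) > 1e-9) {
    stop("`window` must be a positive multiple of 20 s", call. = FALSE)
  }
  b <- as_block(block)
  W <- as.integer(round(window / GRID_PERIOD_S))
  events <- detect_hypotension(rec, b, map_threshold = map_threshold)
  alerts <- detect_alerts(rec, b, threshold)

  # earliest usable alert anchor at or after `pos`: inside a qualifying
  # exceedance run, not inside an ongoing hypotensive event
  next_anchor <- function(pos) {
    for (k in seq_len(nrow(alerts))) {
      if (alerts$end[k] <= pos) next
      a <- max(alerts$start[k], pos)
      repeat {
        # strictly inside: an anchor exactly at onset still predicts (TTE 0)
        inside <- which(events$start < a & a < events$end)
        if (!length(inside)) break
        a <- events$end[inside[1]]  # event under way: earliest re-alert
      }
      if (a < alerts$end[k]) return(a)
    }
    NA_integer_
  }

  rows <- vector("list", 0L)
  emit <- function(window_start, label, alert = NA_integer_,
                   onset = NA_integer_) {
    rows[[length(rows) + 1L]] <<- data.frame(
      window_start = as.integer(window_start), label = label,
      alert_sample = as.integer(alert),
      event_onset_sample = as.integer(onset),
      time_to_event_s = if (!is.na(alert) && !is.na(onset)) {
        (onset - alert) * GRID_PERIOD_S
      } else NA_real_)
  }

  pos <- b[["start"]]
  bend <- b[["end"]]
  while (pos < bend) {
    a <- next_anchor(pos)
    e_k <- which(events$start >= pos)
    e <- if (length(e_k)) events$start[e_k[1]] else NA_integer_
    horizon <- pos + W
    if (!is.na(a) && a < horizon && (is.na(e) || a <= e)) {
      # alert window anchored at a
      hit <- which(events$start >= a & events$start < a + W)
      if (length(hit)) {
        emit(a, "TP", alert = a, onset = events$start[hit[1]])
        pos <- events$end[hit[1]]
      } else {
        emit(a, "FP", alert = a)
        pos <- a + W
      }
    } else if (!is.na(e) && e < horizon) {
      # unpredicted event inside a negative span
      emit(pos, "FN", onset = e)
      pos <- events$end[e_k[1]]
    } else if (horizon <= bend) {
      emit(pos, "TN")
      pos <- horizon
    } else {
      break  # trailing partial span with no alert and no event
    }
  }

  out <- if (length(rows)) do.call(rbind, rows) else {
    data.frame(window_start = integer(), label = character(),
               alert_sample = integer(), event_onset_sample = integer(),
               time_to_event_s = numeric())
  }
  out$label <- factor(out$label, levels = c("TP", "TN", "FP", "FN"))
  attr(out, "threshold") <- threshold
  attr(out, "window") <- window
  attr(out, "recording_id") <- rec$recording_id
  class(out) <- c("hypoval_labels", "data.frame")
  out
}

#' Export window labels as a plain table
#'
#' Converts a label set to a plain data frame in seconds, suitable for
#' writing as delimited text.
#'
#' @param labels output of [forward_validate()].
#' @param rec the recording the labels came from (for id and start time).
#' @return A data frame with columns `recording_id`, `window_start_s`,
#'   `label`, `alert_s`, `event_onset_s`, `tte_s`.
#' @export
labels_as_table <- function(labels, rec) {
  t0 <- rec$start_time
  p <- rec$sample_period
  data.frame(
    recording_id = rec$recording_id,
    window_start_s = t0 + (labels$window_start - 1L) * p,
    label = as.character(labels$label),
    alert_s = t0 + (labels$alert_sample - 1L) * p,
    event_onset_s = t0 + (labels$event_onset_sample - 1L) * p,
    tte_s = labels$time_to_event_s)
}
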