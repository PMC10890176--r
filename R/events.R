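# maximal runs of TRUE in a logical vector, as half-open [start, end)
# restricted to runs of at least min_len samples
true_runs <- function(x, min_len = 1L) {
  r <- rle(x)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= min_len
  data.frame(start = starts[keep], end = ends[keep] + 1L)
}

#' Detect hypotensive events within an analysis block
#'
#' A hypotensive event is MAP below 65 mmHg sustained for at least one
#' minute, i.e. at least 3 consecutive 20-s samples below threshold. The
#' event ends at the first subsequent sample with MAP at or above
#' threshold (or at the block end). Shorter dips (1-2 samples) are
#' ignored.
#'
#' @param rec a censored [recording()].
#' @param block one analysis block (single row of [analysis_blocks()]
#'   output, or `c(start, end)` half-open sample indices).
#' @param map_threshold hypotension threshold, mmHg (default 65).
#' @param min_duration minimum sustained duration, seconds (default 60).
#' @return A data frame with one row per event: `start`, `end` (half-open
#'   sample indices into the recording) and `duration_s`.
#' @examples
#' rec <- recording(map = c(70, 64, 64, 64, 70), index = rep(0, 5))
#' detect_hypotension(rec, c(1, 6))
#' @export
detect_hypotension <- function(rec, block, map_threshold = 65,
                               min_duration = 60) {
  stopifnot(inherits(rec, "hypoval_recording"))
  b <- as_block(block)
  min_len <- as.integer(ceiling(min_duration / GRID_PERIOD_S))
  if (b["end"] <= b["start"]) {
    return(data.frame(start = integer(), end = integer(),
                      duration_s = numeric()))
  }
  sl <- b["start"]:(b["end"] - 1L)
  below <- rec$map[sl] < map_threshold
  runs <- true_runs(below, min_len = min_len)
  out <- data.frame(start = runs$start + b[["start"]] - 1L,
                    end = runs$end + b[["start"]] - 1L)
  out$duration_s <- (out$end - out$start) * GRID_PERIOD_S
  out
}

#' Detect index alerts within an analysis block
#'
#' An alert is an exceedance of the chosen index threshold sustained for
#' at least one minute: at least 3 consecutive samples with index
#' strictly greater than the threshold. One alert is reported per maximal
#' exceedance run, anchored at the run's first sample. Because the index
#' is bounded by 100 and the comparison is strict, threshold 100 never
#' alerts.
#'
#' @param rec a censored [recording()].
#' @param block one analysis block (see [detect_hypotension()]).
#' @param threshold alert threshold in index units, `[0, 100]`.
#' @return A data frame with one row per alert: `threshold`, `start`,
#'   `end` (half-open extent of the exceedance run).
#' @export
detect_alerts <- function(rec, block, threshold) {
  stopifnot(inherits(rec, "hypoval_recording"),
            threshold >= 0, threshold <= 100)
  b <- as_block(block)
  if (b["end"] <= b["start"]) {
    return(data.frame(threshold = numeric(), start = integer(),
                      end = integer()))
  }
  sl <- b["start"]:(b["end"] - 1L)
  above <- !is.na(rec$index[sl]) & rec$index[sl] > threshold
  runs <- true_runs(above, min_len = 3L)
  if (nrow(runs) == 0L) {
    return(data.frame(threshold = numeric(), start = integer(),
                      end = integer()))
  }
  data.frame(threshold = threshold,
             start = runs$start + b[["start"]] - 1L,
             end = runs$end + b[["start"]] - 1L)
}
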