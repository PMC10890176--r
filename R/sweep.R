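#' Threshold sweep of forward-validation performance
#'
#' Runs [forward_validate()] for every recording, analysis block and
#' threshold, pools the window labels across the cohort, and computes the
#' full outcome panel per threshold: confusion counts, sensitivity,
#' specificity, PPV and NPV with Wilson intervals, and the time-to-event
#' median and IQR. Deterministic given its inputs.
#'
#' @param cohort list of censored [recording()] objects.
#' @param thresholds index thresholds to evaluate (default 0 to 100 in
#'   steps of 5).
#' @param window prediction window, seconds (default 1200).
#' @param map_threshold hypotension threshold, mmHg.
#' @param min_block minimum analysis-block length, seconds.
#' @param ci_level confidence level for the Wilson intervals.
#' @param per_recording if `TRUE`, return per-recording stratified rows
#'   (an extra `recording_id` column) instead of the pooled panel.
#' @return A data frame of class `hypoval_sweep`, one row per threshold
#'   (per recording when stratified), with the counts and metric columns;
#'   attribute `ci_method` records the interval type.
#' @export
threshold_sweep <- function(cohort, thresholds = seq(0, 100, by = 5),
                            window = 1200, map_threshold = 65,
                            min_block = 0, ci_level = 0.95,
                            per_recording = FALSE) {
  if (inherits(cohort, "hypoval_recording")) cohort <- list(cohort)
  if (length(cohort) == 0L) stop("empty cohort", call. = FALSE)
  stopifnot(all(vapply(cohort, inherits, TRUE, "hypoval_recording")))

  blocks <- lapply(cohort, analysis_blocks, min_block = min_block)
  one_threshold <- function(thr, recs, blks) {
    labs <- list()
    for (i in seq_along(recs)) {
      bl <- blks[[i]]
      for (k in seq_len(nrow(bl))) {
        labs[[length(labs) + 1L]] <-
          as.data.frame(forward_validate(recs[[i]], bl[k, ],
                                         threshold = thr, window = window,
                                         map_threshold = map_threshold))
      }
    }
    labels <- if (length(labs)) do.call(rbind, labs) else {
      data.frame(label = character(), time_to_event_s = numeric())
    }
    counts <- tally(labels)
    row <- data.frame(threshold = thr, t(counts), n_windows = sum(counts))
    if (sum(counts) > 0) {
      row <- cbind(row, classification_metrics(counts, ci_level))
    } else {
      empty <- classification_metrics(c(tp = 0, tn = 1, fp = 0, fn = 0))
      empty[1, ] <- NA_real_
      row <- cbind(row, empty)
    }
    tte <- tte_summary(labels)
    row$tte_median <- tte$median
    row$tte_q25 <- tte$q25
    row$tte_q75 <- tte$q75
    row$n_tte <- tte$n
    row
  }

  if (per_recording) {
    out <- do.call(rbind, lapply(seq_along(cohort), function(i) {
      rows <- do.call(rbind, lapply(thresholds, one_threshold,
                                    recs = cohort[i], blks = blocks[i]))
      cbind(recording_id = cohort[[i]]$recording_id, rows)
    }))
  } else {
    out <- do.call(rbind, lapply(thresholds, one_threshold,
                                 recs = cohort, blks = blocks))
  }
  rownames(out) <- NULL
  attr(out, "ci_method") <- "wilson"
  attr(out, "window") <- window
  class(out) <- c("hypoval_sweep", "data.frame")
  out
}

#' ROC curve and AUROC from a threshold sweep
#'
#' Builds the receiver operating characteristic curve from the discrete
#' sweep: one `(1 - specificity, sensitivity)` point per threshold with
#' both metrics defined, plus anchor points (0,0) and (1,1). The area
#' under the curve is computed by trapezoidal integration over the
#' FPR-sorted points; at a duplicated FPR only the highest TPR is kept.
#' No smoothing is applied — only the discrete sweep exists.
#'
#' @param sweep output of [threshold_sweep()].
#' @return A list of class `hypoval_roc` with `points` (data frame
#'   `fpr`, `tpr`, `threshold`) and `auroc`.
#' @export
roc_from_sweep <- function(sweep) {
  ok <- !is.na(sweep$sensitivity) & !is.na(sweep$specificity)
  if (sum(ok) < 1L) {
    stop("no threshold with both sensitivity and specificity defined",
         call. = FALSE)
  }
  pts <- data.frame(fpr = 1 - sweep$specificity[ok],
                    tpr = sweep$sensitivity[ok],
                    threshold = sweep$threshold[ok])
  pts <- rbind(pts, data.frame(fpr = c(0, 1), tpr = c(0, 1),
                               threshold = NA_real_))
  pts <- pts[order(pts$fpr, pts$tpr), , drop = FALSE]
  # duplicate FPRs: keep the maximal TPR for integration
  keep <- rev(!duplicated(rev(pts$fpr)))
  ipts <- pts[keep, , drop = FALSE]
  auroc <- sum(diff(ipts$fpr) * (head(ipts$tpr, -1) + tail(ipts$tpr, -1)) / 2)
  structure(list(points = pts[!is.na(pts$threshold) | !duplicated(pts$fpr), ,
                              drop = FALSE],
                 integration_points = ipts,
                 auroc = auroc),
            class = "hypoval_roc")
}

#' @export
print.hypoval_roc <- function(x, ...) {
  cat(sprintf("<hypoval_roc> %d points, AUROC = %.3f\n",
              nrow(x$points), x$auroc))
  invisible(x)
}

#' Cohort descriptive summary
#'
#' Totals and per-patient median [IQR] descriptives of the kind reported
#' for monitored cohorts: monitored time, hypotensive event counts and
#' durations, cumulative hypotension, percent of monitored time spent
#' hypotensive, and the time-weighted average depth of hypotension.
#'
#' @param cohort list of censored [recording()] objects.
#' @param map_threshold hypotension threshold, mmHg.
#' @param min_block minimum analysis-block length, seconds.
#' @return A list of class `hypoval_cohort_summary`.
#' @export
cohort_summary <- function(cohort, map_threshold = 65, min_block = 0) {
  if (inherits(cohort, "hypoval_recording")) cohort <- list(cohort)
  if (length(cohort) == 0L) stop("empty cohort", call. = FALSE)
  per <- lapply(cohort, function(rec) {
    bl <- analysis_blocks(rec, min_block = min_block)
    evs <- do.call(rbind, c(
      lapply(seq_len(nrow(bl)), function(k) {
        detect_hypotension(rec, bl[k, ], map_threshold = map_threshold)
      }),
      list(data.frame(start = integer(), end = integer(),
                      duration_s = numeric()))))
    segs <- segment_count(bl)
    hypo_segs <- sum(evs$end - evs$start)
    twa <- if (segs > 0) {
      # duration-weighted TWA across this recording's blocks
      num <- sum(vapply(seq_len(nrow(bl)), function(k) {
        twa_hypotension(rec, bl[k, ], map_threshold) *
          (bl$end[k] - bl$start[k])
      }, numeric(1)))
      num / segs
    } else NA_real_
    list(n_events = nrow(evs), event_durations = evs$duration_s,
         segs = segs, hypo_min = sum(evs$duration_s) / 60,
         pct_hypo = if (segs > 0) 100 * hypo_segs / segs else NA_real_,
         twa = twa)
  })
  med_iqr <- function(x) {
    x <- x[!is.na(x)]
    if (!length(x)) return(c(median = NA_real_, q25 = NA_real_,
                             q75 = NA_real_))
    q <- unname(quantile(x, c(0.5, 0.25, 0.75), type = 7))
    c(median = q[1], q25 = q[2], q75 = q[3])
  }
  all_durs <- unlist(lapply(per, `[[`, "event_durations"))
  structure(list(
    n_recordings = length(cohort),
    total_monitored_h = sum(vapply(per, `[[`, numeric(1), "segs")) *
      GRID_PERIOD_S / 3600,
    total_segments = sum(vapply(per, `[[`, numeric(1), "segs")),
    n_events = sum(vapply(per, `[[`, numeric(1), "n_events")),
    total_hypotension_min = sum(vapply(per, `[[`, numeric(1), "hypo_min")),
    events_per_patient = med_iqr(vapply(per, `[[`, numeric(1), "n_events")),
    event_duration_min = med_iqr(all_durs / 60),
    cumulative_hypotension_min = med_iqr(vapply(per, `[[`, numeric(1),
                                                "hypo_min")),
    percent_time_hypotensive = med_iqr(vapply(per, `[[`, numeric(1),
                                              "pct_hypo")),
    twa_mmhg = med_iqr(vapply(per, `[[`, numeric(1), "twa"))),
    class = "hypoval_cohort_summary")
}

#' @export
print.hypoval_cohort_summary <- function(x, ...) {
  cat("<hypoval_cohort_summary>\n")
  cat(sprintf("  %d recordings, %.1f h monitored (%d segments)\n",
              x$n_recordings, x$total_monitored_h, x$total_segments))
  cat(sprintf("  %d hypotensive events, %.1f min total\n",
              x$n_events, x$total_hypotension_min))
  cat(sprintf("  events/patient %.0f [%.0f-%.0f]; event duration %.1f [%.1f-%.1f] min\n",
              x$events_per_patient[1], x$events_per_patient[2],
              x$events_per_patient[3], x$event_duration_min[1],
              x$event_duration_min[2], x$event_duration_min[3]))
  cat(sprintf("  TWA %.2f [%.2f-%.2f] mmHg\n",
              x$twa_mmhg[1], x$twa_mmhg[2], x$twa_mmhg[3]))
  invisible(x)
}
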