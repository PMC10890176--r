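#' Tally window labels into confusion counts
#'
#' @param labels output of [forward_validate()] (one or more label sets
#'   at a single threshold, row-bound).
#' @return Named integer vector `c(tp, tn, fp, fn)`; sums to the number
#'   of labels.
#' @export
tally <- function(labels) {
  lab <- factor(as.character(labels$label), levels = c("TP", "TN", "FP", "FN"))
  counts <- table(lab)
  c(tp = unname(counts[["TP"]]), tn = unname(counts[["TN"]]),
    fp = unname(counts[["FP"]]), fn = unname(counts[["FN"]]))
}

#' Wilson score interval for a binomial proportion
#'
#' The Wilson score interval is used for all classification-metric
#' confidence bounds; unlike the Wald interval it behaves sensibly at
#' small counts and near 0 or 1, and it always contains the point
#' estimate.
#'
#' @param x number of successes.
#' @param n number of trials.
#' @param level confidence level (default 0.95).
#' @return `c(lower, upper)`; `c(NA, NA)` when `n == 0`.
#' @examples
#' wilson_ci(9, 10)  # c(0.596, 0.982) to 3 decimals
#' @export
wilson_ci <- function(x, n, level = 0.95) {
  if (n == 0) return(c(lower = NA_real_, upper = NA_real_))
  z <- qnorm(1 - (1 - level) / 2)
  p <- x / n
  denom <- 1 + z^2 / n
  center <- (p + z^2 / (2 * n)) / denom
  half <- z / denom * sqrt(p * (1 - p) / n + z^2 / (4 * n^2))
  # exact bounds at the boundary counts, avoiding floating-point slivers
  lower <- if (x == 0) 0 else max(0, center - half)
  upper <- if (x == n) 1 else min(1, center + half)
  c(lower = lower, upper = upper)
}

#' Classification metrics with Wilson confidence intervals
#'
#' Computes sensitivity `tp/(tp+fn)`, specificity `tn/(tn+fp)`, positive
#' predictive value `tp/(tp+fp)` and negative predictive value
#' `tn/(tn+fn)` from window-level confusion counts. A ratio whose
#' denominator is zero is undefined and reported as `NA`, never as 0.
#'
#' @param counts named vector from [tally()] (`tp`, `tn`, `fp`, `fn`).
#' @param ci_level confidence level for the Wilson intervals.
#' @return A one-row data frame with each metric and its `_lo`/`_hi`
#'   bounds.
#' @export
classification_metrics <- function(counts, ci_level = 0.95) {
  counts <- counts[c("tp", "tn", "fp", "fn")]
  stopifnot(all(counts >= 0))
  if (sum(counts) == 0) {
    stop("cannot compute metrics from all-zero counts", call. = FALSE)
  }
  ratio <- function(x, n) {
    if (n == 0) {
      c(est = NA_real_, lo = NA_real_, hi = NA_real_)
    } else {
      ci <- wilson_ci(x, n, ci_level)
      c(est = x / n, lo = unname(ci[1]), hi = unname(ci[2]))
    }
  }
  sens <- ratio(counts[["tp"]], counts[["tp"]] + counts[["fn"]])
  spec <- ratio(counts[["tn"]], counts[["tn"]] + counts[["fp"]])
  ppv <- ratio(counts[["tp"]], counts[["tp"]] + counts[["fp"]])
  npv <- ratio(counts[["tn"]], counts[["tn"]] + counts[["fn"]])
  data.frame(
    sensitivity = sens[["est"]], sensitivity_lo = sens[["lo"]],
    sensitivity_hi = sens[["hi"]],
    specificity = spec[["est"]], specificity_lo = spec[["lo"]],
    specificity_hi = spec[["hi"]],
    ppv = ppv[["est"]], ppv_lo = ppv[["lo"]], ppv_hi = ppv[["hi"]],
    npv = npv[["est"]], npv_lo = npv[["lo"]], npv_hi = npv[["hi"]])
}

#' Time-to-event summary over true-positive windows
#'
#' Median and interquartile range of the time from alert to event onset,
#' over TP windows. Quantiles use linear interpolation between order
#' statistics (R's default type 7).
#'
#' @param labels output of [forward_validate()] (possibly row-bound
#'   across recordings).
#' @return A list with `median`, `q25`, `q75` (seconds) and `n`; all
#'   quantiles `NA` when there are no TP windows (absent, not zero).
#' @export
tte_summary <- function(labels) {
  tte <- labels$time_to_event_s[as.character(labels$label) == "TP"]
  tte <- tte[!is.na(tte)]
  if (length(tte) == 0L) {
    return(list(median = NA_real_, q25 = NA_real_, q75 = NA_real_, n = 0L))
  }
  q <- unname(quantile(tte, c(0.25, 0.5, 0.75), type = 7))
  list(median = q[2], q25 = q[1], q75 = q[3], n = length(tte))
}

#' Time-weighted average depth of hypotension
#'
#' Area under the MAP threshold (default 65 mmHg) divided by the duration
#' of the measurement period: the average number of mmHg spent below the
#' threshold, in mmHg. Zero when MAP never drops below the threshold.
#'
#' @param rec a censored [recording()].
#' @param block one analysis block (see [detect_hypotension()]).
#' @param map_threshold threshold, mmHg (default 65).
#' @return TWA in mmHg.
#' @examples
#' rec <- recording(map = rep(60, 10), index = rep(0, 10))
#' twa_hypotension(rec, c(1, 11))  # 5 mmHg regardless of duration
#' @export
twa_hypotension <- function(rec, block, map_threshold = 65) {
  stopifnot(inherits(rec, "hypoval_recording"))
  b <- as_block(block)
  if (b["end"] <= b["start"]) stop("empty analysis block", call. = FALSE)
  m <- rec$map[b["start"]:(b["end"] - 1L)]
  mean(pmax(0, map_threshold - m))
}
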