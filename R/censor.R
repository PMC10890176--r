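#' Default artifact-censoring rule set
#'
#' Invasive arterial-line recordings carry artifacts — line flushes and
#' blood sampling (pressure spikes/steps), transducer disconnections
#' (flatlines), positional changes — that would corrupt event labeling.
#' The censoring rules mask samples likely affected; values are never
#' altered, only the validity mask. The rule names and parameters are:
#'
#' \describe{
#'   \item{`map_range`}{MAP outside `[map_min, map_max]` mmHg
#'     (physiologically implausible; default 20-200).}
#'   \item{`map_jump`}{absolute MAP change greater than `max_jump` mmHg
#'     between consecutive samples; both samples are censored
#'     (default 30 mmHg per 20-s step).}
#'   \item{`flatline`}{more than `max_run` consecutive identical MAP
#'     values (default 15 samples = 5 min); the whole run is censored.
#'     A true arterial signal never repeats to the last digit that long.}
#'   \item{`missing_index`}{samples with no index value.}
#' }
#'
#' @param map_min,map_max plausible MAP range, mmHg.
#' @param max_jump maximum plausible MAP change per sample, mmHg.
#' @param max_run longest plausible run of identical MAP values, samples.
#' @param require_index censor samples with a missing index value.
#' @return A named list of rules, one parameter list per rule name, for
#'   [censor_artifacts()].
#' @export
censor_rules <- function(map_min = 20, map_max = 200, max_jump = 30,
                         max_run = 15, require_index = TRUE) {
  stopifnot(is.finite(map_min), is.finite(map_max), map_min < map_max,
            is.finite(max_jump), max_jump > 0,
            is.finite(max_run), max_run >= 1)
  rules <- list(
    map_range = list(map_min = map_min, map_max = map_max),
    map_jump = list(max_jump = max_jump),
    flatline = list(max_run = max_run)
  )
  if (require_index) rules$missing_index <- list()
  rules
}

#' Censor artifact-affected samples
#'
#' Applies a set of censoring rules to a recording, returning a copy whose
#' validity mask is `FALSE` wherever any rule fires. MAP and index values
#' are preserved. The operation is idempotent and never re-validates a
#' sample that was already invalid.
#'
#' Per-rule censoring counts are attached as attribute `censor_counts`
#' and reported via `message()` when `options(hypoval.verbose = TRUE)`.
#'
#' @param rec a [recording()].
#' @param rules rule set from [censor_rules()]; an empty list is the
#'   identity. Unknown rule names raise an error.
#' @return The censored recording.
#' @examples
#' rec <- recording(map = c(75, 75, 250, 75), index = rep(10, 4))
#' censor_artifacts(rec)$valid
#' @export
censor_artifacts <- function(rec, rules = censor_rules()) {
  stopifnot(inherits(rec, "hypoval_recording"))
  known <- c("map_range", "map_jump", "flatline", "missing_index")
  unknown <- setdiff(names(rules), known)
  if (length(unknown)) {
    stop("unknown censor rule(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  n <- n_samples(rec)
  map <- rec$map
  fired <- matrix(FALSE, nrow = n, ncol = length(rules),
                  dimnames = list(NULL, names(rules)))
  for (rule in names(rules)) {
    p <- rules[[rule]]
    hit <- switch(rule,
      map_range = !is.na(map) & (map < p$map_min | map > p$map_max),
      map_jump = {
        d <- abs(diff(map))
        jump <- !is.na(d) & d > p$max_jump
        h <- logical(n)
        h[which(jump)] <- TRUE       # first sample of the pair
        h[which(jump) + 1L] <- TRUE  # second sample of the pair
        h
      },
      flatline = {
        r <- rle(ifelse(is.na(map), NA_real_, map))
        ends <- cumsum(r$lengths)
        starts <- ends - r$lengths + 1L
        h <- logical(n)
        long <- which(r$lengths > p$max_run & !is.na(r$values))
        for (k in long) h[starts[k]:ends[k]] <- TRUE
        h
      },
      missing_index = is.na(rec$index)
    )
    fired[, rule] <- hit
  }
  counts <- colSums(fired & rec$valid)
  out <- rec
  out$valid <- rec$valid & !apply(fired, 1L, any)
  attr(out, "censor_counts") <- counts
  if (isTRUE(getOption("hypoval.verbose"))) {
    message(sprintf("[%s] censored: %s", rec$recording_id,
                    paste(sprintf("%s=%d", names(counts), counts),
                          collapse = ", ")))
  }
  out
}

#' Contiguous analysis blocks of a censored recording
#'
#' Returns the maximal runs of valid samples, ordered by start, dropping
#' runs shorter than `min_block` seconds. Block bounds are 1-based and
#' half-open: samples `start, ..., end - 1` belong to the block.
#'
#' @param rec a (typically censored) [recording()].
#' @param min_block minimum block length in seconds; must be a
#'   nonnegative multiple of 20.
#' @return A data frame with columns `start`, `end` (half-open sample
#'   indices) and `duration_s`.
#' @export
analysis_blocks <- function(rec, min_block = 0) {
  stopifnot(inherits(rec, "hypoval_recording"))
  if (min_block < 0 || abs(min_block %% GRID_PERIOD_S) > 1e-9) {
    stop("`min_block` must be a nonnegative multiple of 20 s", call. = FALSE)
  }
  r <- rle(rec$valid)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & (r$lengths * GRID_PERIOD_S >= min_block)
  out <- data.frame(start = starts[keep], end = ends[keep] + 1L)
  out$duration_s <- (out$end - out$start) * GRID_PERIOD_S
  attr(out, "recording_id") <- rec$recording_id
  out
}

#' Count 20-second segments covered by analysis blocks
#'
#' @param blocks a data frame from [analysis_blocks()] (columns `start`,
#'   `end`, half-open), or any disjoint block set in that form.
#' @return Total number of valid 20-s segments; equals monitored hours
#'   times 180.
#' @examples
#' segment_count(data.frame(start = 1, end = 181))  # one hour -> 180
#' @export
segment_count <- function(blocks) {
  if (nrow(blocks) == 0L) return(0L)
  as.integer(sum(blocks$end - blocks$start))
}

# normalise a block argument: single-row data.frame or c(start, end)
as_block <- function(block) {
  if (is.data.frame(block)) {
    stopifnot(nrow(block) == 1L)
    c(start = as.integer(block$start), end = as.integer(block$end))
  } else {
    stopifnot(length(block) == 2L)
    c(start = as.integer(block[[1]]), end = as.integer(block[[2]]))
  }
}
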