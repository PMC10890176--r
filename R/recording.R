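#' Construct a MAP/index recording on the 20-second grid
#'
#' A recording holds one patient's aligned mean arterial pressure (MAP,
#' mmHg) and prediction-index series, both sampled every 20 seconds,
#' together with a validity mask. Sample `k` represents the half-open
#' interval `[start_time + (k-1)*20, start_time + k*20)` seconds.
#'
#' @param map numeric vector of MAP values (mmHg); `NA` allowed (sample is
#'   marked invalid).
#' @param index numeric vector of prediction-index values in `[0, 100]`;
#'   `NA` allowed (missing index).
#' @param valid logical validity mask; defaults to `!is.na(map)`.
#' @param recording_id opaque identifier string.
#' @param start_time time of the first sample, in seconds.
#' @param sample_period grid period in seconds; only 20 is supported.
#'
#' @return An object of class `hypoval_recording`: a list with elements
#'   `recording_id`, `start_time`, `sample_period`, `map`, `index`,
#'   `valid`.
#' @examples
#' rec <- recording(map = c(70, 64, 64, 64, 70), index = rep(10, 5))
#' rec
#' @export
recording <- function(map, index, valid = NULL, recording_id = "rec",
                      start_time = 0, sample_period = GRID_PERIOD_S) {
  map <- as.numeric(map)
  index <- as.numeric(index)
  if (length(map) < 1L) {
    stop("a recording needs at least one sample", call. = FALSE)
  }
  if (length(index) != length(map)) {
    stop("`map` and `index` must have identical length", call. = FALSE)
  }
  if (is.null(valid)) valid <- !is.na(map)
  valid <- as.logical(valid)
  if (length(valid) != length(map) || anyNA(valid)) {
    stop("`valid` must be a logical mask of the same length, without NA",
         call. = FALSE)
  }
  if (sample_period != GRID_PERIOD_S) {
    stop("only the 20-second grid is supported", call. = FALSE)
  }
  bad <- which(!is.na(index) & (index < 0 | index > 100))
  if (length(bad)) {
    stop(sprintf("index value out of [0, 100] at sample %d (value %g)",
                 bad[1], index[bad[1]]), call. = FALSE)
  }
  structure(
    list(recording_id = as.character(recording_id)[1],
         start_time = as.numeric(start_time)[1],
         sample_period = sample_period,
         map = map, index = index, valid = valid),
    class = "hypoval_recording"
  )
}

#' @export
print.hypoval_recording <- function(x, ...) {
  cat(sprintf("<hypoval_recording '%s'>\n", x$recording_id))
  cat(sprintf("  %d samples on a %ds grid (%.2f h), %d valid (%.1f%%)\n",
              length(x$map), x$sample_period,
              length(x$map) * x$sample_period / 3600,
              sum(x$valid), 100 * mean(x$valid)))
  invisible(x)
}

#' Number of samples in a recording
#' @param rec a [recording()].
#' @return integer sample count.
#' @export
n_samples <- function(rec) length(rec$map)

#' Read a recording from a delimited text file
#'
#' Reads a CSV/TSV file with a time column (seconds, strictly increasing),
#' a MAP column (mmHg) and an index column, and places it on a strict
#' 20-second grid. Gaps in the source grid are filled with missing samples
#' marked invalid. Files sampled faster than 20 s are accepted only when
#' the period divides 20 s exactly, and are decimated by taking the last
#' value in each 20-second bin; any other grid is rejected rather than
#' silently resampled.
#'
#' @param path file path.
#' @param dialect named character vector mapping roles to column names;
#'   default `c(time = "time_s", map = "map_mmhg", index = "hpi")`.
#' @param sep field separator; `NULL` (default) auto-detects tab vs comma
#'   from the header line.
#' @param recording_id identifier; defaults to the file name without
#'   extension.
#' @return A [recording()].
#' @export
load_recording <- function(path,
                           dialect = c(time = "time_s", map = "map_mmhg",
                                       index = "hpi"),
                           sep = NULL, recording_id = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (is.null(sep)) {
    header <- readLines(path, n = 1L)
    sep <- if (grepl("\t", header)) "\t" else ","
  }
  df <- tryCatch(
    read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE),
    error = function(e) stop(sprintf("parse error in '%s': %s",
                                     path, conditionMessage(e)),
                             call. = FALSE)
  )
  need <- dialect[c("time", "map", "index")]
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    stop(sprintf("parse error in '%s': missing column(s) %s",
                 path, paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  t <- as.numeric(df[[need[["time"]]]])
  map <- as.numeric(df[[need[["map"]]]])
  idx <- as.numeric(df[[need[["index"]]]])
  if (anyNA(t)) {
    stop(sprintf("parse error in '%s': non-numeric time at data line %d",
                 path, which(is.na(t))[1]), call. = FALSE)
  }
  if (any(diff(t) <= 0)) {
    stop(sprintf("time not strictly increasing in '%s' at data line %d",
                 path, which(diff(t) <= 0)[1] + 1L), call. = FALSE)
  }
  if (any(!is.na(idx) & (idx < 0 | idx > 100))) {
    k <- which(!is.na(idx) & (idx < 0 | idx > 100))[1]
    stop(sprintf("index value out of [0, 100] in '%s' at data line %d (%g)",
                 path, k, idx[k]), call. = FALSE)
  }

  p <- GRID_PERIOD_S
  off <- t - t[1]
  on_grid <- all(abs(off %% p) < 1e-9 | abs(off %% p - p) < 1e-9)
  if (!on_grid) {
    d <- round(diff(t), 9)
    src <- unique(d)
    if (length(src) == 1L && src > 0 && abs(p %% src) < 1e-9 && src < p) {
      # finer regular grid: decimate by last value in each 20-s bin
      keep <- abs((off + src) %% p) < 1e-9
      t <- t[keep]; map <- map[keep]; idx <- idx[keep]
      off <- t - t[1]
    } else {
      stop(sprintf("time grid in '%s' is not 20 s nor an exact divisor of it",
                   path), call. = FALSE)
    }
  }
  slot <- as.integer(round(off / p)) + 1L
  n <- max(slot)
  full_map <- rep(NA_real_, n)
  full_idx <- rep(NA_real_, n)
  full_map[slot] <- map
  full_idx[slot] <- idx
  if (is.null(recording_id)) {
    recording_id <- sub("\\.[^.]*$", "", basename(path))
  }
  recording(map = full_map, index = full_idx, valid = !is.na(full_map),
            recording_id = recording_id, start_time = t[1])
}

#' Write a recording back to delimited text
#'
#' Values are serialised with 17 significant digits so that a
#' load/write/load cycle reproduces valid samples bit-identically.
#'
#' @param rec a [recording()].
#' @param path output file path.
#' @param sep field separator (default tab).
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path, sep = "\t") {
  stopifnot(inherits(rec, "hypoval_recording"))
  n <- n_samples(rec)
  t <- rec$start_time + (seq_len(n) - 1L) * rec$sample_period
  fmt <- function(x) ifelse(is.na(x), "NA", sprintf("%.17g", x))
  lines <- c(paste("time_s", "map_mmhg", "hpi", sep = sep),
             paste(fmt(t), fmt(rec$map), fmt(rec$index), sep = sep))
  writeLines(lines, path)
  invisible(path)
}
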