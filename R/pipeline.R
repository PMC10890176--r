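#' Eligibility filter: minimum uninterrupted monitoring time
#'
#' Keeps recordings with at least one contiguous valid block of
#' `min_duration_h` hours after censoring — the common eligibility gate
#' for monitored cohorts ("uninterrupted" is read as a single contiguous
#' block, not cumulative valid time). Every input recording lands in
#' exactly one of the two outputs.
#'
#' @param cohort list of censored [recording()] objects.
#' @param min_duration_h minimum uninterrupted duration, hours
#'   (default 3).
#' @return A list with `eligible` (list of recordings) and `excluded`
#'   (data frame `recording_id`, `reason`, `longest_block_h`).
#' @export
eligibility_filter <- function(cohort, min_duration_h = 3) {
  if (inherits(cohort, "hypoval_recording")) cohort <- list(cohort)
  keep <- logical(length(cohort))
  longest <- numeric(length(cohort))
  for (i in seq_along(cohort)) {
    bl <- analysis_blocks(cohort[[i]], min_block = 0)
    longest[i] <- if (nrow(bl)) max(bl$duration_s) / 3600 else 0
    keep[i] <- longest[i] >= min_duration_h
  }
  excluded <- data.frame(
    recording_id = vapply(cohort[!keep], `[[`, character(1),
                          "recording_id"),
    reason = rep(sprintf("< %g h of uninterrupted valid data",
                         min_duration_h), sum(!keep)),
    longest_block_h = longest[!keep])
  list(eligible = cohort[keep], excluded = excluded)
}

#' Run the full validation pipeline with provenance
#'
#' Loads a cohort from a directory of delimited recordings (or generates
#' a synthetic one), censors artifacts, applies the eligibility gate,
#' sweeps alert thresholds, and writes the outcome panel:
#' \itemize{
#'   \item `sweep.tsv` — per-threshold metrics and raw TP/TN/FP/FN
#'     counts,
#'   \item `roc.json` — ROC points and AUROC,
#'   \item `cohort_summary.json` — descriptive panel,
#'   \item `exclusions.tsv` — recordings failing the eligibility gate,
#'   \item `manifest.json` — config snapshot, inputs, versions and
#'     per-stage counts, sufficient to re-run the analysis identically.
#' }
#' Given a fixed generator seed, `sweep.tsv`, `roc.json` and
#' `cohort_summary.json` are byte-identical across reruns.
#'
#' @param input_dir directory of CSV/TSV recordings, or `NULL` to use
#'   `generator_config`.
#' @param generator_config a [synthetic_config()], used when
#'   `input_dir` is `NULL`.
#' @param output_dir output directory (created if needed).
#' @param thresholds alert thresholds to sweep.
#' @param window prediction window, seconds.
#' @param map_threshold hypotension threshold, mmHg.
#' @param min_eligible_h eligibility gate, hours of uninterrupted data.
#' @param min_block minimum analysis-block length, seconds (blocks
#'   shorter than this are dropped before labeling).
#' @param rules censor rule set from [censor_rules()].
#' @param dialect column-name map for [load_recording()].
#' @return The manifest, invisibly. Errors if no recording passes the
#'   eligibility gate.
#' @export
run_validation <- function(input_dir = NULL, generator_config = NULL,
                           output_dir, thresholds = seq(0, 100, by = 5),
                           window = 1200, map_threshold = 65,
                           min_eligible_h = 3, min_block = 0,
                           rules = censor_rules(),
                           dialect = c(time = "time_s", map = "map_mmhg",
                                       index = "hpi")) {
  if (is.null(input_dir) && is.null(generator_config)) {
    stop("provide `input_dir` or `generator_config`", call. = FALSE)
  }
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)

  if (!is.null(input_dir)) {
    files <- sort(list.files(input_dir, pattern = "\\.(csv|tsv|txt)$",
                             full.names = TRUE))
    if (length(files) == 0L) {
      stop("no eligible recordings: input directory contains no ",
           "CSV/TSV files", call. = FALSE)
    }
    raw <- lapply(files, function(f) {
      tryCatch(load_recording(f, dialect = dialect),
               error = function(e) {
                 warning(sprintf("skipping '%s': %s", f,
                                 conditionMessage(e)), call. = FALSE)
                 NULL
               })
    })
    raw <- Filter(Negate(is.null), raw)
    inputs <- list(kind = "files", files = basename(files))
  } else {
    cohort <- generate_cohort(generator_config)
    raw <- cohort$recordings
    inputs <- list(kind = "generator",
                   seed = generator_config$seed,
                   n_recordings = generator_config$n_recordings)
  }

  censored <- lapply(raw, censor_artifacts, rules = rules)
  gate <- eligibility_filter(censored, min_duration_h = min_eligible_h)
  if (length(gate$eligible) == 0L) {
    stop("no eligible recordings after the eligibility gate", call. = FALSE)
  }

  sweep <- threshold_sweep(gate$eligible, thresholds = thresholds,
                           window = window, map_threshold = map_threshold,
                           min_block = min_block)
  roc <- roc_from_sweep(sweep)
  summ <- cohort_summary(gate$eligible, map_threshold = map_threshold,
                         min_block = min_block)

  write_tsv <- function(df, path) {
    df_out <- df
    num <- vapply(df_out, is.numeric, TRUE)
    df_out[num] <- lapply(df_out[num],
                          function(x) ifelse(is.na(x), NA,
                                             sprintf("%.10g", x)))
    write.table(df_out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                na = "-")
  }
  write_tsv(as.data.frame(sweep), file.path(output_dir, "sweep.tsv"))
  write_tsv(gate$excluded, file.path(output_dir, "exclusions.tsv"))
  jsonlite::write_json(
    list(points = roc$points, auroc = roc$auroc,
         ci_method = attr(sweep, "ci_method")),
    file.path(output_dir, "roc.json"), auto_unbox = TRUE, digits = NA,
    na = "null")
  jsonlite::write_json(unclass(summ),
                       file.path(output_dir, "cohort_summary.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")

  manifest <- list(
    package_version = as.character(packageVersion("hypoval")),
    r_version = as.character(getRversion()),
    created = format(Sys.time(), tz = "UTC"),
    inputs = inputs,
    parameters = list(thresholds = thresholds, window_s = window,
                      map_threshold = map_threshold,
                      min_eligible_h = min_eligible_h,
                      min_block = min_block,
                      censor_rules = rules),
    generator_config = if (!is.null(generator_config)) {
      unclass(generator_config)
    } else NULL,
    stage_counts = list(
      n_input = length(raw),
      n_eligible = length(gate$eligible),
      n_excluded = nrow(gate$excluded),
      censored_samples = sum(vapply(censored, function(r) {
        sum(attr(r, "censor_counts"))
      }, numeric(1))),
      n_windows_total = sum(sweep$n_windows)))
  jsonlite::write_json(manifest, file.path(output_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, na = "null",
                       pretty = TRUE)
  invisible(manifest)
}

#' Read pipeline configuration from a YAML file
#'
#' Maps a key-value config file onto the arguments of
#' [run_validation()], [censor_rules()] and [synthetic_config()].
#' Unknown keys raise an error rather than being ignored.
#'
#' @param path YAML file path.
#' @return A named list of argument lists: `validation`, `censor`,
#'   `generator`.
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  known <- c("validation", "censor", "generator")
  unknown <- setdiff(names(cfg), known)
  if (length(unknown)) {
    stop("unknown config section(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  check_args <- function(given, fn, where) {
    bad <- setdiff(names(given), names(formals(fn)))
    if (length(bad)) {
      stop(sprintf("unknown %s option(s): %s", where,
                   paste(bad, collapse = ", ")), call. = FALSE)
    }
    given
  }
  list(validation = check_args(cfg$validation %||% list(), run_validation,
                               "validation"),
       censor = check_args(cfg$censor %||% list(), censor_rules, "censor"),
       generator = check_args(cfg$generator %||% list(), synthetic_config,
                              "generator"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
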