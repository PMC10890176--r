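#' Configuration for the synthetic cohort generator
#'
#' Defines the generative model for seeded synthetic MAP/index recordings
#' with known ground truth. Defaults emulate the descriptive statistics
#' of a monitored PACU/ICU cohort: 11.3-hour recordings, a median of
#' about 4 hypotensive events per patient, per-event durations with a
#' median near 2 minutes (log-normal), and a bounded index that rises
#' ahead of events with a configurable lead time.
#'
#' The MAP baseline is an Ornstein-Uhlenbeck process (mean
#' `baseline_map`, correlation time `ou_tau_s`, stationary SD
#' `ou_sd`), softly reflected at `map_floor` so that hypotension occurs
#' only where events are injected — making ground truth exact. Events
#' are smooth dips whose sub-65 crossing times fall strictly between
#' grid samples, so the number of sub-threshold samples is controlled
#' analytically.
#'
#' Index modes:
#' \describe{
#'   \item{`perfect`}{100 from `lead_time` seconds before each event
#'     onset until the event end, 0 elsewhere.}
#'   \item{`lagged`}{logistic transform of the MAP deficit
#'     `lead_time` seconds ahead, strictly inside (0, 100); noise-free.}
#'   \item{`noisy`}{`lagged` plus Gaussian noise of SD `index_noise`,
#'     clipped to [0, 100].}
#'   \item{`random`}{a smooth autocorrelated signal independent of MAP.}
#' }
#'
#' @param n_recordings number of recordings in the cohort.
#' @param duration_h recording duration, hours (default 11.3).
#' @param event_rate hypotensive events per hour (default 4/11.3, i.e.
#'   about 4 events per default-length recording).
#' @param event_duration_meanlog,event_duration_sdlog log-normal
#'   parameters of event duration in seconds (defaults give median 120 s,
#'   quartiles near 1.5 and 2.7 min).
#' @param event_depth_meanlog,event_depth_sdlog log-normal parameters of
#'   the nadir depth below 65 mmHg (median 8 mmHg); capped at 45 mmHg so
#'   MAP stays positive.
#' @param baseline_map mean MAP, mmHg.
#' @param ou_tau_s baseline correlation time, seconds.
#' @param ou_sd baseline stationary standard deviation, mmHg.
#' @param map_floor reflection floor for the baseline, mmHg (> 65).
#' @param index_mode one of `"perfect"`, `"lagged"`, `"noisy"`,
#'   `"random"`.
#' @param lead_time seconds by which the index rises ahead of event
#'   onset (default 180).
#' @param index_noise Gaussian noise SD in index units (`noisy` mode).
#' @param artifact_rate artifacts per hour (spike, step or flatline).
#' @param seed integer RNG seed; a fixed seed makes the whole cohort
#'   bit-reproducible.
#' @return A list of class `hypoval_synth_config`.
#' @export
synthetic_config <- function(n_recordings = 282,
                             duration_h = 11.3,
                             event_rate = 4 / 11.3,
                             event_duration_meanlog = log(120),
                             event_duration_sdlog = 0.45,
                             event_depth_meanlog = log(8),
                             event_depth_sdlog = 0.5,
                             baseline_map = 80,
                             ou_tau_s = 300,
                             ou_sd = 4,
                             map_floor = 68,
                             index_mode = c("lagged", "perfect", "noisy",
                                            "random"),
                             lead_time = 180,
                             index_noise = 5,
                             artifact_rate = 0,
                             seed = 1L) {
  index_mode <- match.arg(index_mode)
  stopifnot(n_recordings >= 1, duration_h > 0, event_rate >= 0,
            lead_time >= 0, index_noise >= 0, artifact_rate >= 0,
            ou_sd > 0, ou_tau_s > 0, map_floor > 65,
            baseline_map > map_floor)
  cfg <- list(n_recordings = as.integer(n_recordings),
              duration_h = duration_h, event_rate = event_rate,
              event_duration_meanlog = event_duration_meanlog,
              event_duration_sdlog = event_duration_sdlog,
              event_depth_meanlog = event_depth_meanlog,
              event_depth_sdlog = event_depth_sdlog,
              baseline_map = baseline_map, ou_tau_s = ou_tau_s,
              ou_sd = ou_sd, map_floor = map_floor,
              index_mode = index_mode, lead_time = lead_time,
              index_noise = index_noise, artifact_rate = artifact_rate,
              seed = as.integer(seed))
  # events shorter than 1 min (3 samples) cannot be detected downstream
  p_short <- stats::plnorm(60, event_duration_meanlog, event_duration_sdlog)
  if (p_short > 0.25) {
    warning(sprintf(paste0("%.0f%% of simulated event durations fall below ",
                           "60 s and will be undetectable"), 100 * p_short),
            call. = FALSE)
  }
  class(cfg) <- "hypoval_synth_config"
  cfg
}

# deterministic per-recording seed below 2^31
substream_seed <- function(seed, recording_index) {
  as.integer((as.double(seed %% 65536L) * 1103515L + 12345 +
                2654435 * as.double(recording_index)) %% 2147483647)
}

#' Generate one synthetic recording with ground truth
#'
#' Deterministic for a fixed `(seed, recording_index)` pair; the global
#' RNG state is restored on exit.
#'
#' @param cfg a [synthetic_config()].
#' @param recording_index 0-based index of the recording within the
#'   cohort (selects the RNG substream).
#' @return A list with elements `recording` (a [recording()]) and
#'   `truth` (ground truth: data frames `events` with `onset`, `end`,
#'   `duration_s`, `depth`, and `artifacts` with `start`, `end`, `kind`).
#' @export
generate_recording <- function(cfg, recording_index = 0L) {
  stopifnot(inherits(cfg, "hypoval_synth_config"))
  old_seed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                   envir = globalenv())
  })
  set.seed(substream_seed(cfg$seed, recording_index))

  p <- GRID_PERIOD_S
  n <- as.integer(round(cfg$duration_h * 3600 / p))
  tgrid <- (seq_len(n) - 1) * p

  ## baseline: AR(1) discretisation of an OU process, reflected at floor
  phi <- exp(-p / cfg$ou_tau_s)
  innov_sd <- cfg$ou_sd * sqrt(1 - phi^2)
  z <- numeric(n)
  z[1] <- rnorm(1, 0, cfg$ou_sd)
  eps <- rnorm(n - 1, 0, innov_sd)
  if (n > 1) for (k in 2:n) z[k] <- phi * z[k - 1] + eps[k - 1]
  map <- cfg$baseline_map + z
  map <- cfg$map_floor + abs(map - cfg$map_floor)

  ## event placement: Poisson count, uniform onsets, enforced separation
  lead_k <- as.integer(round(cfg$lead_time / p))
  n_ev <- rpois(1, cfg$event_rate * cfg$duration_h)
  margin_lo <- lead_k + 16L       # room for the index rise + a lead-in
  margin_hi <- 16L
  events <- data.frame(onset = integer(), end = integer(),
                       duration_s = numeric(), depth = numeric())
  if (n_ev > 0 && n - margin_lo - margin_hi > 10L) {
    durs <- rlnorm(n_ev, cfg$event_duration_meanlog,
                   cfg$event_duration_sdlog)
    ks <- pmax(1L, as.integer(round(durs / p)))
    depths <- pmin(45, rlnorm(n_ev, cfg$event_depth_meanlog,
                              cfg$event_depth_sdlog))
    cand <- sort(sample.int(n - margin_lo - margin_hi, n_ev,
                            replace = TRUE) + margin_lo)
    gap <- lead_k + 9L            # keep consecutive alerts separable
    placed <- integer(0)
    last_end <- -Inf
    kept <- logical(n_ev)
    for (i in seq_len(n_ev)) {
      o <- cand[i]
      if (o <= last_end + gap) next
      if (o + ks[i] + margin_hi > n) next
      kept[i] <- TRUE
      placed <- c(placed, o)
      last_end <- o + ks[i]
    }
    if (any(kept)) {
      events <- data.frame(onset = placed, end = placed + ks[kept],
                           duration_s = ks[kept] * p, depth = depths[kept])
    }
  }

  ## inject smooth dips: sub-65 crossings at onset-10 s and end-10 s,
  ## so samples onset..end-1 are strictly below 65 and neighbours above
  for (i in seq_len(nrow(events))) {
    o <- events$onset[i]; e <- events$end[i]; depth <- events$depth[i]
    t_on <- tgrid[o] - p / 2
    t_off <- t_on + (e - o) * p
    ramp <- 60                    # shoulder length, seconds
    lo <- max(1L, o - as.integer(ceiling(ramp / p)) - 1L)
    hi <- min(n, e + as.integer(ceiling(ramp / p)) + 1L)
    for (k in lo:hi) {
      t <- tgrid[k]
      if (t >= t_on && t <= t_off) {
        core <- 65 - depth * sin(pi * (t - t_on) / (t_off - t_on))
        map[k] <- core
      } else if (t > t_on - ramp && t < t_on) {
        w <- (t_on - t) / ramp    # 0 at onset crossing, 1 at shoulder
        ws <- 0.5 * (1 - cos(pi * w))
        map[k] <- 65 + (map[k] - 65) * ws
      } else if (t > t_off && t < t_off + ramp) {
        w <- (t - t_off) / ramp
        ws <- 0.5 * (1 - cos(pi * w))
        map[k] <- 65 + (map[k] - 65) * ws
      }
    }
  }

  ## index signal
  idx <- switch(cfg$index_mode,
    perfect = {
      v <- numeric(n)
      for (i in seq_len(nrow(events))) {
        a <- max(1L, events$onset[i] - lead_k)
        v[a:(events$end[i] - 1L)] <- 100
      }
      v
    },
    lagged = ,
    noisy = {
      fut <- if (lead_k > 0) c(map[(lead_k + 1L):n], rep(map[n], lead_k))
             else map
      v <- 100 * plogis((68 - fut) / 2)
      if (cfg$index_mode == "noisy" && cfg$index_noise > 0) {
        v <- v + rnorm(n, 0, cfg$index_noise)
      }
      pmin(100, pmax(0, v))
    },
    random = {
      # index-independent AR(1) on the same time scale as the MAP process
      phi_r <- exp(-p / cfg$ou_tau_s)
      zz <- numeric(n)
      zz[1] <- rnorm(1, 0, 1.5)
      ee <- rnorm(n - 1, 0, 1.5 * sqrt(1 - phi_r^2))
      if (n > 1) for (k in 2:n) zz[k] <- phi_r * zz[k - 1] + ee[k - 1]
      100 * plogis(zz)
    })

  ## artifacts: spike, step, flatline — placed clear of event dips
  artifacts <- data.frame(start = integer(), end = integer(),
                          kind = character())
  n_art <- rpois(1, cfg$artifact_rate * cfg$duration_h)
  if (n_art > 0) {
    forbidden <- logical(n)
    for (i in seq_len(nrow(events))) {
      lo <- max(1L, events$onset[i] - lead_k - 6L)
      hi <- min(n, events$end[i] + 6L)
      forbidden[lo:hi] <- TRUE
    }
    kinds <- sample(c("spike", "step", "flatline"), n_art, replace = TRUE)
    for (i in seq_len(n_art)) {
      len <- switch(kinds[i], spike = 1L, step = 6L, flatline = 20L)
      s <- sample.int(max(1L, n - len - 2L), 1L) + 1L
      span <- s:(s + len - 1L)
      if (any(forbidden[span]) || s + len > n) next
      map[span] <- switch(kinds[i],
                          spike = 230,
                          step = map[span] + 45,
                          flatline = rep(round(map[s], 1), len))
      artifacts <- rbind(artifacts,
                         data.frame(start = s, end = s + len,
                                    kind = kinds[i]))
    }
  }

  rec <- recording(map = map, index = idx,
                   recording_id = sprintf("synth-%04d", recording_index),
                   start_time = 0)
  list(recording = rec,
       truth = list(events = events, artifacts = artifacts))
}

#' Generate a synthetic cohort
#'
#' Each recording is drawn from an independent, deterministic RNG
#' substream of the configured seed, so cohorts are reproducible (and
#' would remain so under parallel generation).
#'
#' @param cfg a [synthetic_config()].
#' @return A list of class `hypoval_cohort` with elements `recordings`
#'   (list of [recording()]) and `truth` (list of ground-truth objects,
#'   same order), plus the `config`.
#' @export
generate_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "hypoval_synth_config"), cfg$n_recordings >= 1)
  gen <- lapply(seq_len(cfg$n_recordings) - 1L,
                function(i) generate_recording(cfg, i))
  structure(list(recordings = lapply(gen, `[[`, "recording"),
                 truth = lapply(gen, `[[`, "truth"),
                 config = cfg),
            class = "hypoval_cohort")
}
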