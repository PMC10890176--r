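# Deliberately naive sample-by-sample re-implementation of the forward
# scan, sharing no code with forward_validate(); used as a differential
# oracle. Every run/event/alert question is answered by walking samples.

oracle_forward_validate <- function(rec, block, threshold, window = 1200) {
  b1 <- as.integer(block[[1]])
  b2 <- as.integer(block[[2]])
  map <- rec$map
  idx <- rec$index
  W <- as.integer(window / 20)

  below <- function(k) k >= b1 && k < b2 && !is.na(map[k]) && map[k] < 65
  above <- function(k) {
    k >= b1 && k < b2 && !is.na(idx[k]) && idx[k] > threshold
  }

  # maximal below-65 run containing k, as c(start, end_exclusive),
  # NULL unless it qualifies as an event (>= 3 samples)
  event_run_at <- function(k) {
    if (!below(k)) return(NULL)
    a <- k
    while (below(a - 1)) a <- a - 1
    z <- k
    while (below(z + 1)) z <- z + 1
    if (z - a + 1 >= 3) c(a, z + 1) else NULL
  }
  is_onset <- function(k) {
    r <- event_run_at(k)
    !is.null(r) && r[1] == k
  }

  # alert active at k: inside a >threshold run of length >= 3 and not
  # strictly inside an ongoing event
  alert_active <- function(k) {
    if (!above(k)) return(FALSE)
    a <- k
    while (above(a - 1)) a <- a - 1
    z <- k
    while (above(z + 1)) z <- z + 1
    if (z - a + 1 < 3) return(FALSE)
    r <- event_run_at(k)
    is.null(r) || r[1] == k
  }

  rows <- list()
  push <- function(ws, lab, al = NA, on = NA) {
    rows[[length(rows) + 1L]] <<- data.frame(
      window_start = as.integer(ws), label = lab,
      alert_sample = as.integer(al), event_onset_sample = as.integer(on),
      time_to_event_s = if (!is.na(al) && !is.na(on)) 20 * (on - al)
                        else NA_real_)
  }

  pos <- b1
  while (pos < b2) {
    a <- NA_integer_
    k <- pos
    while (k < min(pos + W, b2)) {
      if (alert_active(k)) { a <- k; break }
      k <- k + 1L
    }
    e <- NA_integer_
    k <- pos
    while (k < b2) {
      if (is_onset(k)) { e <- k; break }
      k <- k + 1L
    }
    if (!is.na(a) && (is.na(e) || a <= e)) {
      hit <- NA_integer_
      k <- a
      while (k < min(a + W, b2)) {
        if (is_onset(k)) { hit <- k; break }
        k <- k + 1L
      }
      if (!is.na(hit)) {
        push(a, "TP", al = a, on = hit)
        pos <- event_run_at(hit)[2]
      } else {
        push(a, "FP", al = a)
        pos <- a + W
      }
    } else if (!is.na(e) && e < pos + W) {
      push(pos, "FN", on = e)
      pos <- event_run_at(e)[2]
    } else if (pos + W <= b2) {
      push(pos, "TN")
      pos <- pos + W
    } else {
      break
    }
  }

  if (length(rows)) {
    out <- do.call(rbind, rows)
  } else {
    out <- data.frame(window_start = integer(), label = character(),
                      alert_sample = integer(),
                      event_onset_sample = integer(),
                      time_to_event_s = numeric())
  }
  out$label <- factor(out$label, levels = c("TP", "TN", "FP", "FN"))
  out
}
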