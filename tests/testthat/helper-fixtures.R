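# in-code fixtures shared across test files

# recording from raw vectors; index defaults to an uninformative constant
make_rec <- function(map, index = rep(10, length(map)), ...) {
  recording(map = map, index = index, ...)
}

# messy random trace for differential tests: autocorrelated MAP that
# crosses 65 mmHg repeatedly, autocorrelated index with sustained runs
random_recording <- function(n, seed, id = "rand") {
  set.seed(seed)
  map <- numeric(n)
  map[1] <- 70
  for (k in 2:n) map[k] <- 70 + 0.9 * (map[k - 1] - 70) + rnorm(1, 0, 4)
  idx <- numeric(n)
  idx[1] <- 50
  for (k in 2:n) idx[k] <- 50 + 0.92 * (idx[k - 1] - 50) + rnorm(1, 0, 10)
  idx <- pmin(100, pmax(0, idx))
  recording(map = map, index = idx, recording_id = id)
}

block_of <- function(rec) c(1L, n_samples(rec) + 1L)

# strip class/metadata so label frames compare on content only
plain_labels <- function(lab) {
  lab <- as.data.frame(lab)
  for (a in c("threshold", "window", "recording_id")) attr(lab, a) <- NULL
  rownames(lab) <- NULL
  lab
}
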