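# Independent brute-force oracles, written as literal transcriptions of the
# classification rules, deliberately sharing no code with the package.

# Per-interval state labels by explicit scanning: maximal same-state
# stretches, moving stretches broken at sign reversals, 5-frame cutoffs.
oracleLabels <- function(x, eps = 0.5, minRun = 5, minPause = 5) {
  dx <- diff(x)
  n <- length(dx)
  moving <- abs(dx) > eps
  sgn <- sign(dx)
  lab <- character(n)
  i <- 1L
  while (i <= n) {
    j <- i
    if (moving[i]) {
      while (j < n && moving[j + 1L] && sgn[j + 1L] == sgn[i]) j <- j + 1L
      lab[i:j] <- if (j - i + 1L >= minRun) {
        if (sgn[i] > 0) "run_antero" else "run_retro"
      } else "oscillation"
    } else {
      while (j < n && !moving[j + 1L]) j <- j + 1L
      lab[i:j] <- if (j - i + 1L >= minPause) "pause" else "oscillation"
    }
    i <- j + 1L
  }
  lab
}

# Expand a segment table into per-interval labels (runs carry direction).
segmentsToLabels <- function(seg, nIntervals) {
  lab <- rep(NA_character_, nIntervals)
  for (j in seq_len(nrow(seg))) {
    st <- seg$state[j]
    if (st == "run")
      st <- if (seg$direction[j] == "anterograde") "run_antero" else
        "run_retro"
    lab[(seg$start_frame[j] + 1L):(seg$end_frame[j] + 1L)] <- st
  }
  lab
}

# Random integer-position track of a given number of samples.
randomTrack <- function(nSamples, maxStep = 2L) {
  x0 <- sample(50:150, 1L)
  cumsum(c(x0, sample(-maxStep:maxStep, nSamples - 1L, replace = TRUE)))
}

trackDf <- function(x, id = "t1") {
  data.frame(track_id = id, frame = seq_along(x) - 1L, x_px = x)
}
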