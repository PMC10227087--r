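# Shared fixtures and independent brute-force oracles.

# Small optics for fast frame-mode tests.
opt_small <- function(noise_sd = 2) {
  optics_model(d_min = 10, d_max = 28, frame_shape = c(32, 32),
               background_level = 2, noise_sd = noise_sd)
}

test_subject <- function(sbp = 120, dbp = 80, ...) {
  virtual_subject(sbp_true = sbp, dbp_true = dbp, ...)
}

# Frame with a filled disc at an integer-lattice centre (explicit loops, no
# vectorized mask) — independent of render_frame.
disc_frame_loops <- function(n, cx, cy, r, value, background = 0) {
  f <- matrix(background, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if ((i - cy)^2 + (j - cx)^2 <= r^2) f[i, j] <- value
    }
  }
  f
}

# Exhaustive pixel-scan area oracle: explicit double loop over pixels.
area_oracle <- function(frame, threshold = 20) {
  count <- 0L
  for (i in seq_len(nrow(frame))) {
    for (j in seq_len(ncol(frame))) {
      if (frame[i, j] > threshold) count <- count + 1L
    }
  }
  count
}

# Brute-force pulse-amplitude oracle: enumerate all interior local extrema
# with explicit loops, compute prominence by explicit scans, filter, pair
# each surviving peak with the minima towards its neighbours, and average
# complete pulses. Mirrors the documented rules but shares no code with the
# implementation.
pulse_oracle <- function(x, fs, min_prominence = 0.5, min_gap_s = 1 / 3) {
  n <- length(x)
  peaks <- integer(0)
  for (i in 2:(n - 1)) {
    if (x[i] > x[i - 1] && x[i] >= x[i + 1]) peaks <- c(peaks, i)
  }
  prom <- numeric(length(peaks))
  for (k in seq_along(peaks)) {
    i <- peaks[k]
    lmin <- x[i]
    j <- i - 1
    while (j >= 1 && x[j] <= x[i]) {
      lmin <- min(lmin, x[j]); j <- j - 1
    }
    rmin <- x[i]
    j <- i + 1
    while (j <= n && x[j] <= x[i]) {
      rmin <- min(rmin, x[j]); j <- j + 1
    }
    prom[k] <- x[i] - max(lmin, rmin)
  }
  peaks <- peaks[prom >= min_prominence]
  if (length(peaks) == 0) return(list(amplitude = 0, n_pulses = 0L))
  keep <- integer(0)
  for (i in peaks[order(x[peaks], decreasing = TRUE)]) {
    if (all(abs(keep - i) >= min_gap_s * fs)) keep <- c(keep, i)
  }
  peaks <- sort(keep)
  gaps <- numeric(0)
  for (k in seq_along(peaks)[-1]) gaps <- c(gaps, peaks[k] - peaks[k - 1])
  period <- if (length(gaps)) median(gaps) else min_gap_s * fs
  amps <- numeric(0)
  for (k in seq_along(peaks)) {
    i <- peaks[k]
    if (i - 1 < period / 4 || n - i < period / 4) next
    lo <- if (k == 1) 1 else peaks[k - 1]
    hi <- if (k == length(peaks)) n else peaks[k + 1]
    ltr <- lo - 1 + which.min(x[lo:i])
    rtr <- i - 1 + which.min(x[i:hi])
    tr <- numeric(0)
    if (ltr > 1) tr <- c(tr, x[ltr])
    if (rtr < n) tr <- c(tr, x[rtr])
    if (length(tr) == 0) next
    amps <- c(amps, x[i] - mean(tr))
  }
  if (length(amps) == 0) return(list(amplitude = 0, n_pulses = 0L))
  list(amplitude = mean(amps), n_pulses = length(amps))
}

# Random smooth cardiac-like signal for oracle cross-checks.
random_pulse_signal <- function(seed, fs = 30, dur = 5) {
  set.seed(seed)
  t <- seq(0, dur - 1 / fs, by = 1 / fs)
  f <- runif(1, 0.8, 1.6)
  a <- runif(1, 2, 6)
  h2 <- runif(1, 0, 0.3)
  phi <- runif(1, 0, 2 * pi)
  a * (-cos(2 * pi * f * t + phi) + h2 * cos(4 * pi * f * t + 1))
}
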