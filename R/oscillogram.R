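# Oscillogram construction: band-pass the per-level PPG, average the
# peak-to-trough amplitude of complete pulses via peak prominence, attach
# the pressure axis, exclude the endpoint levels, normalize, and screen
# subjects.

#' Band-pass filter for PPG series
#'
#' Zero-phase (forward-backward) Butterworth band-pass with the 0.5--10 Hz
#' cardiac passband. The series mean is removed before filtering so the
#' large DC offset of raw brightness does not drive edge transients.
#'
#' @param x Uniformly sampled PPG series covering at least 2 s.
#' @param frame_rate Sampling rate in Hz; must exceed twice the upper band
#'   edge (> 20 Hz for the default band).
#' @param band Passband in Hz.
#' @return Filtered series, same length, zero mean.
#' @export
bandpass_ppg <- function(x, frame_rate, band = c(0.5, 10)) {
  stopifnot(is.numeric(x), length(band) == 2, band[1] > 0, band[1] < band[2])
  if (frame_rate <= 2 * band[2]) {
    stop(sprintf("frame_rate must exceed %g Hz for a %g Hz band edge",
                 2 * band[2], band[2]), call. = FALSE)
  }
  if (length(x) < 2 * frame_rate) {
    stop("series must cover at least 2 s", call. = FALSE)
  }
  xc <- x - mean(x)
  if (all(xc == 0)) return(xc)
  bf <- signal::butter(2, band / (frame_rate / 2), type = "pass")
  filtfilt_padded(bf, xc, frame_rate)
}

# Zero-phase filtering with odd-reflection end padding, so the filter
# transient of the low-frequency corner decays inside the padding rather
# than inside the (short) analysis window.
filtfilt_padded <- function(bf, x, frame_rate, pad_s = 2) {
  n <- length(x)
  p <- min(n - 1, ceiling(pad_s * frame_rate))
  head_pad <- 2 * x[1] - x[(p + 1):2]
  tail_pad <- 2 * x[n] - x[(n - 1):(n - p)]
  y <- signal::filtfilt(bf, c(head_pad, x, tail_pad))
  y[(p + 1):(p + n)]
}

# Interior local maxima (plateau starts count once).
local_maxima <- function(x) {
  n <- length(x)
  if (n < 3) return(integer(0))
  which(diff(sign(diff(x))) < 0) + 1L
}

# Topographic prominence: on each side, scan to the nearest strictly higher
# sample (or the series end); the base is the minimum over the scan, and
# prominence is peak height above the higher of the two bases.
peak_prominence <- function(x, peaks) {
  n <- length(x)
  vapply(peaks, function(i) {
    j <- i - 1L
    lmin <- x[i]
    while (j >= 1L && x[j] <= x[i]) {
      if (x[j] < lmin) lmin <- x[j]
      j <- j - 1L
    }
    k <- i + 1L
    rmin <- x[i]
    while (k <= n && x[k] <= x[i]) {
      if (x[k] < rmin) rmin <- x[k]
      k <- k + 1L
    }
    x[i] - max(lmin, rmin)
  }, numeric(1))
}

#' Mean peak-to-trough pulse amplitude of one level's filtered PPG
#'
#' Detects pulse peaks with a minimum topographic prominence and a minimum
#' spacing (taller peak wins). A pulse is complete when its peak lies at
#' least a quarter of the pulse period (median peak spacing) away from both
#' window ends, so cycles truncated by the recording window — where the
#' zero-phase filter also distorts the waveform — are excluded. Each
#' complete pulse's amplitude is its peak height above the mean of its
#' genuine flanking troughs (interior signal minima towards the
#' neighbouring peaks); a pulse whose trough on one side is cut off by the
#' window uses the other trough alone. A 5-s window at heart rates 36--84
#' beats/min yields roughly 3--7 complete pulses.
#'
#' @param x Band-pass-filtered PPG series of one recording window.
#' @param frame_rate Sampling rate in Hz.
#' @param min_prominence Prominence floor in grey levels (default 0.5).
#' @param min_gap_s Minimum peak spacing in s (default 1/3 s, i.e. a
#'   180 beats/min ceiling).
#' @return A list: `amplitude` (0 when no complete pulse), `n_pulses`,
#'   `flagged` (`TRUE` when no complete pulse was found).
#' @export
mean_pulse_amplitude <- function(x, frame_rate, min_prominence = 0.5,
                                 min_gap_s = 60 / 180) {
  stopifnot(is.numeric(x), frame_rate > 0)
  n <- length(x)
  empty <- list(amplitude = 0, n_pulses = 0L, flagged = TRUE)
  pk <- local_maxima(x)
  if (length(pk) == 0) return(empty)
  prom <- peak_prominence(x, pk)
  pk <- pk[prom >= min_prominence]
  if (length(pk) == 0) return(empty)
  # enforce minimum spacing, keeping taller peaks first
  min_gap <- min_gap_s * frame_rate
  keep <- integer(0)
  for (i in pk[order(x[pk], decreasing = TRUE)]) {
    if (all(abs(keep - i) >= min_gap)) keep <- c(keep, i)
  }
  pk <- sort(keep)
  period <- if (length(pk) >= 2) median(diff(pk)) else min_gap
  margin <- period / 4
  amps <- numeric(0)
  for (j in seq_along(pk)) {
    i <- pk[j]
    if (i - 1 < margin || n - i < margin) next  # truncated by the window
    lo <- if (j == 1L) 1L else pk[j - 1L]
    hi <- if (j == length(pk)) n else pk[j + 1L]
    ltr <- lo - 1L + which.min(x[lo:i])
    rtr <- i - 1L + which.min(x[i:hi])
    troughs <- c(if (ltr > 1L) x[ltr], if (rtr < n) x[rtr])
    if (length(troughs) == 0) next
    amps <- c(amps, x[i] - mean(troughs))
  }
  if (length(amps) == 0) return(empty)
  list(amplitude = mean(amps), n_pulses = length(amps), flagged = FALSE)
}

#' Build the subsampled oscillogram of a session
#'
#' One point per force level: the level's PPG window is band-pass filtered,
#' its mean pulse amplitude computed by [mean_pulse_amplitude()], and the
#' pressure axis attached by mapping the level's median force scale through
#' the spring mechanics.
#'
#' @param levels Per-level series from [session_levels()].
#' @param spring,geom Mechanics models for the pressure axis.
#' @param band Passband in Hz for [bandpass_ppg()].
#' @param min_prominence Prominence floor in grey levels.
#' @return An `oscillogram` data frame ordered by force: `level`,
#'   `force_scale`, `pressure_mmHg`, `amplitude`, `n_pulses`, `flagged`;
#'   attributes `n_raw` and `normalized = FALSE`.
#' @export
build_oscillogram <- function(levels, spring = spring_model(),
                              geom = contact_geometry(), band = c(0.5, 10),
                              min_prominence = 0.5) {
  fs <- attr(levels, "frame_rate")
  if (is.null(fs)) stop("levels must carry a frame_rate attribute",
                        call. = FALSE)
  idx <- vapply(levels, `[[`, numeric(1), "level_index")
  expected <- seq_len(max(idx))
  gaps <- setdiff(expected, idx)
  if (length(gaps)) {
    stop(sprintf("missing levels: %s", paste(gaps, collapse = ", ")),
         call. = FALSE)
  }
  rows <- lapply(levels, function(lv) {
    ppg <- lv$ppg
    if (any(is.na(ppg))) ppg[is.na(ppg)] <- mean(ppg, na.rm = TRUE)
    pa <- mean_pulse_amplitude(bandpass_ppg(ppg, fs, band), fs,
                               min_prominence)
    sc <- median(lv$force_scale)
    data.frame(level = lv$level_index, force_scale = sc,
               pressure_mmHg = pressure_from_scale(sc, spring, geom),
               amplitude = pa$amplitude, n_pulses = pa$n_pulses,
               flagged = pa$flagged)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$force_scale), ]
  rownames(out) <- NULL
  structure(out, n_raw = nrow(out), normalized = FALSE,
            class = c("oscillogram", "data.frame"))
}

#' Endpoint exclusion and amplitude normalization
#'
#' Drops the lowest and highest force levels (at the lowest force the finger
#' can leave the clip; at the highest the spring bottoms out) and min--max
#' rescales the remaining amplitudes to `[0, 1]`. A divide-by-max variant is
#' available as `method = "maxdiv"`.
#'
#' @param osc An `oscillogram` from [build_oscillogram()].
#' @param method `"minmax"` (default) or `"maxdiv"`.
#' @return The reduced, normalized `oscillogram` (attribute
#'   `normalized = TRUE`).
#' @export
exclude_and_normalize <- function(osc, method = c("minmax", "maxdiv")) {
  method <- match.arg(method)
  stopifnot(inherits(osc, "oscillogram"))
  if (nrow(osc) < 3) stop("need at least 3 oscillogram points", call. = FALSE)
  n_raw <- attr(osc, "n_raw")
  out <- osc[order(osc$force_scale), ][-c(1, nrow(osc)), ]
  a <- out$amplitude
  if (max(a) == min(a)) {
    stop("degenerate oscillogram: all amplitudes equal", call. = FALSE)
  }
  out$amplitude <- switch(method,
    minmax = (a - min(a)) / (max(a) - min(a)),
    maxdiv = a / max(a))
  rownames(out) <- NULL
  structure(out, n_raw = n_raw, normalized = TRUE,
            class = c("oscillogram", "data.frame"))
}

#' Screen a subject for inclusion
#'
#' A subject is excluded when the raw oscillogram shows no usable pulse
#' (maximum amplitude below `amp_floor`) or when the reference pulse
#' pressure exceeds 80 mmHg.
#'
#' @param osc Raw (non-normalized) `oscillogram`.
#' @param sbp_ref,dbp_ref Reference pressures in mmHg.
#' @param amp_floor Minimum usable amplitude in grey levels (default 1).
#' @param pp_max Pulse-pressure exclusion threshold in mmHg (default 80).
#' @return An object of class `screening_result`: `retained` flag and
#'   `reason` in `{"ok", "no_pulse", "pulse_pressure_gt_80"}`.
#' @export
screen_subject <- function(osc, sbp_ref, dbp_ref, amp_floor = 1,
                           pp_max = 80) {
  stopifnot(inherits(osc, "oscillogram"))
  stop_if_not_scalar(sbp_ref, "sbp_ref")
  stop_if_not_scalar(dbp_ref, "dbp_ref")
  reason <- if (max(osc$amplitude) < amp_floor) {
    "no_pulse"
  } else if (sbp_ref - dbp_ref > pp_max) {
    "pulse_pressure_gt_80"
  } else {
    "ok"
  }
  structure(list(retained = reason == "ok", reason = reason),
            class = "screening_result")
}
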