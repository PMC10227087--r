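# Per-frame feature extraction: the three quantities the measurement app
# derives from each camera frame — equalized-image disc area (force), raw
# in-disc mean brightness (PPG), and the proportional force scale.

AREA_THRESHOLD <- 20L   # area: pixels strictly above this (8-bit) count
PPG_BAND <- c(20L, 254L)  # PPG: raw pixels inside this closed interval

check_frame <- function(frame) {
  if (!is.matrix(frame) || !is.numeric(frame)) {
    stop("frame must be a numeric matrix", call. = FALSE)
  }
  if (any(frame < 0 | frame > 255)) {
    stop("frame values must be 8-bit (0-255)", call. = FALSE)
  }
  invisible(frame)
}

#' Global histogram equalization of an 8-bit frame
#'
#' Standard CDF remapping: a pixel of value `v` maps to
#' `round((cdf(v) - cdf_min) / (n - cdf_min) * 255)` where `cdf_min` is the
#' CDF at the lowest occupied grey level. Pixel counts are conserved and a
#' constant frame is returned unchanged. Applied before disc-area detection
#' to remove between-subject baseline differences; the PPG mean always uses
#' the raw frame.
#'
#' @param frame Integer matrix of grey levels 0--255.
#' @return Equalized integer matrix of the same shape.
#' @export
equalize_histogram <- function(frame) {
  check_frame(frame)
  v <- as.integer(round(frame))
  counts <- tabulate(v + 1L, nbins = 256L)
  cdf <- cumsum(counts)
  n <- length(v)
  cdf_min <- min(cdf[counts > 0])
  if (cdf_min == n) return(matrix(v, nrow(frame), ncol(frame)))
  map <- as.integer(round((cdf - cdf_min) / (n - cdf_min) * 255))
  matrix(map[v + 1L], nrow(frame), ncol(frame))
}

#' Projection-disc area of an (equalized) frame
#'
#' Count of pixels strictly above grey level 20. The frame is expected to be
#' histogram-equalized already; the function itself applies only the
#' threshold.
#'
#' @param frame Integer matrix of grey levels 0--255.
#' @return Area in pixels.
#' @export
detect_projection_area <- function(frame) {
  check_frame(frame)
  sum(frame > AREA_THRESHOLD)
}

#' Disc diameter from its pixel area
#'
#' @param area Area in px.
#' @return Diameter in px: `2 * sqrt(area / pi)`.
#' @export
diameter_from_area <- function(area) {
  if (any(area < 0)) stop("area must be >= 0", call. = FALSE)
  2 * sqrt(area / pi)
}

#' PPG sample of a raw frame
#'
#' Mean grey level over pixels inside the closed band `[20, 254]`: the disc
#' interior without the dark background and without saturated pixels. If no
#' pixel qualifies the sample is undefined and `NA` is returned.
#'
#' @param frame Raw (not equalized) integer matrix of grey levels 0--255.
#' @return Mean grey level, or `NA_real_` when no pixel is in band.
#' @export
extract_ppg_sample <- function(frame) {
  check_frame(frame)
  sel <- frame >= PPG_BAND[1] & frame <= PPG_BAND[2]
  if (!any(sel)) {
    bp_log("extract_ppg_sample: no pixel in [%d, %d]; returning NA",
           PPG_BAND[1], PPG_BAND[2])
    return(NA_real_)
  }
  mean(frame[sel])
}

#' Force-scale calibration from resting and fully-pressed disc sizes
#'
#' @param size_at_0pct Disc diameter in px with the finger resting (no
#'   force).
#' @param size_at_100pct Disc diameter in px fully pressed; must exceed
#'   `size_at_0pct`.
#' @return An object of class `force_scale_calibration`.
#' @export
force_scale_calibration <- function(size_at_0pct, size_at_100pct) {
  stop_if_not_scalar(size_at_0pct, "size_at_0pct")
  stop_if_not_scalar(size_at_100pct, "size_at_100pct")
  if (!(size_at_100pct > size_at_0pct && size_at_0pct > 0)) {
    stop("calibration requires size_at_100pct > size_at_0pct > 0",
         call. = FALSE)
  }
  structure(list(size_at_0pct = size_at_0pct,
                 size_at_100pct = size_at_100pct),
            class = "force_scale_calibration")
}

#' Force scale from a measured disc diameter
#'
#' Linear in diameter between the calibrated 0% and 100% sizes, clipped to
#' the diagnostic range `[-10, 110]`%.
#'
#' @param d Diameter in px. Vectorised.
#' @param cal A [force_scale_calibration()].
#' @return Force scale in %.
#' @export
force_scale_from_diameter <- function(d, cal) {
  stopifnot(inherits(cal, "force_scale_calibration"))
  raw <- 100 * (d - cal$size_at_0pct) /
    (cal$size_at_100pct - cal$size_at_0pct)
  clip(raw, -10, 110)
}

#' Low-pass smoothing of the force-scale signal
#'
#' Zero-phase (forward-backward) Butterworth low-pass used to strip the
#' cardiac PPG artifact off the plotted force signal. The default 0.4 Hz
#' cutoff sits below the slowest plausible heart rate (36 beats/min =
#' 0.6 Hz). DC gain is unity.
#'
#' @param x Uniformly sampled force-scale series.
#' @param frame_rate Sampling rate in Hz.
#' @param cutoff Cutoff frequency in Hz.
#' @return Smoothed series of the same length. Series too short for the
#'   filter warm-up are returned unchanged with a warning.
#' @export
smooth_force_signal <- function(x, frame_rate, cutoff = 0.4) {
  stopifnot(is.numeric(x), frame_rate > 2 * cutoff)
  if (length(x) < 24) {
    warning("series shorter than filter warm-up; returned unchanged")
    return(x)
  }
  if (var(x) == 0) return(x)
  bf <- signal::butter(2, cutoff / (frame_rate / 2), type = "low")
  mu <- mean(x)
  mu + filtfilt_padded(bf, x - mu, frame_rate, pad_s = 1 / cutoff)
}

# Single-pass per-frame features without re-validating each call; same
# arithmetic as equalize_histogram + detect_projection_area +
# extract_ppg_sample on an already-validated integer frame.
frame_features_fast <- function(f) {
  v <- as.integer(f)
  n <- length(v)
  counts <- tabulate(v + 1L, nbins = 256L)
  cdf <- cumsum(counts)
  cdf_min <- min(cdf[counts > 0])
  eq <- if (cdf_min == n) v else {
    as.integer(round((cdf - cdf_min) / (n - cdf_min) * 255))[v + 1L]
  }
  sel <- v >= PPG_BAND[1] & v <= PPG_BAND[2]
  c(area = sum(eq > AREA_THRESHOLD),
    ppg = if (any(sel)) mean(v[sel]) else NA_real_)
}

# Calibration as the app would measure it: equalize -> area -> diameter on
# the recorded 0%/100% calibration frames, median over frames.
measure_calibration <- function(recording) {
  stopifnot(inherits(recording, "session_recording"))
  if (recording$mode != "frames" || is.null(recording$calibration$frames)) {
    return(force_scale_calibration(recording$calibration$size0,
                                   recording$calibration$size100))
  }
  med_d <- function(frames) {
    median(vapply(frames, function(f) {
      diameter_from_area(detect_projection_area(equalize_histogram(f)))
    }, numeric(1)))
  }
  force_scale_calibration(med_d(recording$calibration$frames$at_0pct),
                          med_d(recording$calibration$frames$at_100pct))
}

#' Per-frame features of a recorded session
#'
#' Runs the app's extraction chain over every recorded frame: histogram
#' equalization then thresholded area and diameter, force scale against the
#' session's measured 0%/100% calibration, and the raw-frame PPG mean.
#'
#' @param recording A frame-mode `session_recording`.
#' @param cal Optional [force_scale_calibration()]; defaults to the one
#'   measured from the session's calibration frames.
#' @return A data frame with one row per recorded frame: `timestamp`,
#'   `level`, `area`, `diameter`, `force_scale`, `ppg_value`.
#' @export
extract_session_features <- function(recording, cal = NULL) {
  stopifnot(inherits(recording, "session_recording"))
  if (recording$mode != "frames" || length(recording$frames) == 0) {
    stop("extract_session_features needs a non-empty frame-mode recording",
         call. = FALSE)
  }
  if (is.null(cal)) cal <- measure_calibration(recording)
  rows <- lapply(recording$levels, function(lv) {
    feats <- vapply(lv$frame_idx, function(k) {
      frame_features_fast(recording$frames[[k]])
    }, numeric(2))
    d <- diameter_from_area(feats["area", ])
    data.frame(timestamp = lv$t, level = lv$level_index,
               area = feats["area", ], diameter = d,
               force_scale = force_scale_from_diameter(d, cal),
               ppg_value = feats["ppg", ])
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Unified per-level force/PPG series of a session
#'
#' For signal-mode recordings the stored series are returned; for frame-mode
#' recordings the series are measured from the frames via
#' [extract_session_features()]. This is the common input of
#' [build_oscillogram()].
#'
#' @param recording A `session_recording`.
#' @return A list with one element per level: `level_index`, `target_scale`,
#'   `t`, `force_scale`, `ppg`; the sampling rate is attached as attribute
#'   `frame_rate`.
#' @export
session_levels <- function(recording) {
  stopifnot(inherits(recording, "session_recording"))
  if (recording$mode == "signal") {
    out <- lapply(recording$levels, function(lv) {
      lv[c("level_index", "target_scale", "t", "force_scale", "ppg")]
    })
  } else {
    feats <- extract_session_features(recording)
    out <- lapply(recording$levels, function(lv) {
      sel <- feats$level == lv$level_index
      list(level_index = lv$level_index, target_scale = lv$target_scale,
           t = feats$timestamp[sel], force_scale = feats$force_scale[sel],
           ppg = feats$ppg_value[sel])
    })
  }
  attr(out, "frame_rate") <- recording$frame_rate
  out
}
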