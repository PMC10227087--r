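# Virtual subjects and camera optics for the forward model.

#' A virtual subject with known ground-truth blood pressure
#'
#' Holds the physiological parameters the forward model needs: true systolic
#' and diastolic pressure, heart rate, the perfusion gain (peak-to-trough
#' pulse amplitude, in grey levels, of the photoplethysmogram at the envelope
#' maximum), the width of the Gaussian oscillometric envelope, and the
#' baseline brightness of the bloodless projection disc. Mean pressure is
#' derived as `MBP = SBP/3 + 2*DBP/3`.
#'
#' @param sbp_true,dbp_true Systolic/diastolic pressure in mmHg
#'   (`sbp_true > dbp_true`).
#' @param heart_rate Heart rate in beats/min, within `[36, 180]`.
#' @param perfusion_gain Pulse-amplitude scale in grey levels, `>= 0`.
#' @param envelope_width Gaussian envelope standard deviation in mmHg.
#' @param skin_baseline Brightness (0--255) of the disc with no pulse.
#' @param sbp_taper Width in mmHg of the smooth collapse of the envelope just
#'   below systolic pressure; the envelope is exactly 0 at and above SBP.
#' @return An object of class `virtual_subject` with the derived `mbp_true`.
#' @examples
#' s <- virtual_subject(sbp_true = 120, dbp_true = 80)
#' s$mbp_true
#' @export
virtual_subject <- function(sbp_true, dbp_true, heart_rate = 70,
                            perfusion_gain = 10, envelope_width = 20,
                            skin_baseline = 180, sbp_taper = 10) {
  for (nm in c("sbp_true", "dbp_true", "heart_rate", "perfusion_gain",
               "envelope_width", "skin_baseline", "sbp_taper")) {
    stop_if_not_scalar(get(nm), nm)
  }
  if (sbp_true <= dbp_true) stop("sbp_true must exceed dbp_true", call. = FALSE)
  if (heart_rate < 36 || heart_rate > 180) {
    stop("heart_rate must lie in [36, 180] beats/min", call. = FALSE)
  }
  if (perfusion_gain < 0) stop("perfusion_gain must be >= 0", call. = FALSE)
  if (envelope_width <= 0) stop("envelope_width must be > 0", call. = FALSE)
  if (skin_baseline < 0 || skin_baseline > 255) {
    stop("skin_baseline must be a 0-255 grey level", call. = FALSE)
  }
  structure(list(
    sbp_true = sbp_true, dbp_true = dbp_true,
    mbp_true = compute_reference_mbp(sbp_true, dbp_true),
    heart_rate = heart_rate, perfusion_gain = perfusion_gain,
    envelope_width = envelope_width, skin_baseline = skin_baseline,
    sbp_taper = sbp_taper), class = "virtual_subject")
}

#' Pinhole-projection optics model
#'
#' The pinhole sits closer to the camera as the spring compresses, so the
#' projected disc grows; the mapping from compression to disc diameter is
#' linear between `d_min` (no force) and `d_max` (full travel).
#'
#' @param d_min,d_max Disc diameter in px at zero and full compression;
#'   `0 < d_min < d_max <= min(frame_shape)`.
#' @param frame_shape Frame dimensions `c(rows, cols)` in px.
#' @param background_level Mean grey level outside the disc; must stay below
#'   the detection threshold of 20.
#' @param noise_sd Per-pixel Gaussian noise standard deviation in grey levels.
#' @return An object of class `optics_model`.
#' @export
optics_model <- function(d_min = 32, d_max = 100, frame_shape = c(128, 128),
                         background_level = 2, noise_sd = 2) {
  stopifnot(length(frame_shape) == 2, all(frame_shape >= 8))
  stop_if_not_scalar(d_min, "d_min"); stop_if_not_scalar(d_max, "d_max")
  if (!(d_min > 0 && d_min < d_max && d_max <= min(frame_shape))) {
    stop("require 0 < d_min < d_max <= min(frame_shape)", call. = FALSE)
  }
  if (background_level < 0 || background_level >= 20) {
    stop("background_level must be below the detection threshold of 20",
         call. = FALSE)
  }
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  structure(list(d_min = d_min, d_max = d_max,
                 frame_shape = as.integer(frame_shape),
                 background_level = background_level, noise_sd = noise_sd),
            class = "optics_model")
}

# Disc diameter (px) at a given spring compression (mm): linear mapping.
disc_diameter <- function(compression, optics, spring) {
  optics$d_min + (optics$d_max - optics$d_min) *
    (compression / spring$max_travel)
}

#' Population model for synthetic cohorts
#'
#' Defaults follow the summary statistics of the validation cohort the method
#' was designed for (SBP 116.8 +/- 20.3 mmHg, DBP 73.5 +/- 12.3 mmHg), with
#' physiological truncation. Pulse pressure is rejected outside
#' `pp_range` (default 25--80 mmHg: below 25 is non-physiological; above 80
#' is the screening exclusion cap, so a default cohort is fully retainable).
#'
#' @param sbp_mean,sbp_sd,dbp_mean,dbp_sd Reference BP distribution, mmHg.
#' @param bp_cor Correlation between systolic and diastolic draws
#'   (physiologically the two rise together; default 0.6).
#' @param sbp_range,dbp_range,pp_range Truncation intervals, mmHg.
#' @param hr_mean,hr_sd,hr_range Heart-rate distribution, beats/min.
#' @param gain_mean,gain_sd,gain_range Perfusion-gain distribution, grey
#'   levels.
#' @param width_mean,width_sd,width_range Envelope-width distribution, mmHg.
#' @param baseline_mean,baseline_sd,baseline_range Disc-baseline brightness.
#' @param pulseless_gain Perfusion gain assigned to forced no-pulse subjects.
#' @return A list of class `cohort_population`.
#' @export
cohort_population <- function(sbp_mean = 116.8, sbp_sd = 20.3,
                              dbp_mean = 73.5, dbp_sd = 12.3, bp_cor = 0.6,
                              sbp_range = c(85, 175), dbp_range = c(45, 110),
                              pp_range = c(25, 80),
                              hr_mean = 70, hr_sd = 10, hr_range = c(45, 110),
                              gain_mean = 10, gain_sd = 3,
                              gain_range = c(4, 20),
                              width_mean = 20, width_sd = 2.5,
                              width_range = c(12, 30),
                              baseline_mean = 180, baseline_sd = 15,
                              baseline_range = c(120, 220),
                              pulseless_gain = 0.2) {
  structure(as.list(environment()), class = "cohort_population")
}

# One subject draw; SBP/DBP are drawn jointly with correlation bp_cor and
# rejection sampling keeps both pressures and the pulse pressure in range.
draw_subject <- function(pop) {
  repeat {
    sbp <- rnorm(1, pop$sbp_mean, pop$sbp_sd)
    dbp <- pop$dbp_mean +
      pop$bp_cor * pop$dbp_sd / pop$sbp_sd * (sbp - pop$sbp_mean) +
      pop$dbp_sd * sqrt(1 - pop$bp_cor^2) * rnorm(1)
    pp <- sbp - dbp
    ok <- sbp >= pop$sbp_range[1] && sbp <= pop$sbp_range[2] &&
      dbp >= pop$dbp_range[1] && dbp <= pop$dbp_range[2] &&
      pp >= pop$pp_range[1] && pp <= pop$pp_range[2]
    if (ok) break
  }
  draw_trunc <- function(m, s, r) {
    repeat {
      v <- rnorm(1, m, s)
      if (v >= r[1] && v <= r[2]) return(v)
    }
  }
  virtual_subject(
    sbp_true = sbp, dbp_true = dbp,
    heart_rate = draw_trunc(pop$hr_mean, pop$hr_sd, pop$hr_range),
    perfusion_gain = draw_trunc(pop$gain_mean, pop$gain_sd, pop$gain_range),
    envelope_width = draw_trunc(pop$width_mean, pop$width_sd,
                                pop$width_range),
    skin_baseline = draw_trunc(pop$baseline_mean, pop$baseline_sd,
                               pop$baseline_range))
}
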