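# Forward model: oscillometric envelope, PPG waveform, frame rendering,
# and whole-session / cohort synthesis with known ground truth.

#' Oscillometric pulse-amplitude envelope
#'
#' Pulse amplitude as a function of externally applied pressure: a Gaussian
#' centred at the subject's true mean pressure with standard deviation
#' `envelope_width`, scaled by `perfusion_gain`, and multiplied by a smooth
#' cutoff that falls to zero as the applied pressure approaches systolic
#' pressure — above SBP the artery is fully occluded, blood ceases to flow,
#' and the projection stops pulsing.
#'
#' @param applied_pressure Applied contact pressure in mmHg, `>= 0`.
#'   Vectorised.
#' @param subject A [virtual_subject()].
#' @return Peak-to-trough pulse amplitude in grey levels; exactly 0 for
#'   `applied_pressure >= sbp_true`.
#' @examples
#' s <- virtual_subject(120, 80)
#' envelope_amplitude(s$mbp_true, s)   # envelope maximum region
#' envelope_amplitude(130, s)          # above SBP: 0
#' @export
envelope_amplitude <- function(applied_pressure, subject) {
  stopifnot(inherits(subject, "virtual_subject"))
  if (any(!is.finite(applied_pressure)) || any(applied_pressure < 0)) {
    stop("applied_pressure must be >= 0", call. = FALSE)
  }
  g <- exp(-(applied_pressure - subject$mbp_true)^2 /
             (2 * subject$envelope_width^2))
  # smoothstep from 1 at (SBP - taper) down to exactly 0 at SBP
  s <- clip((subject$sbp_true - applied_pressure) / subject$sbp_taper, 0, 1)
  cutoff <- s * s * (3 - 2 * s)
  subject$perfusion_gain * g * cutoff
}

#' Normalized PPG waveform over the cardiac cycle
#'
#' Raised cosine with unit peak-to-trough amplitude and zero mean; an
#' optional second harmonic adds a dicrotic-notch-like inflection (off by
#' default). After adding the harmonic the waveform is renormalized so its
#' peak-to-trough span stays exactly 1.
#'
#' @param phase Cardiac phase in radians. Vectorised.
#' @param dicrotic Relative amplitude of the second harmonic (default 0).
#' @return Waveform values in `[-0.5, 0.5]`.
#' @export
ppg_waveform <- function(phase, dicrotic = 0) {
  w <- 0.5 * cos(phase)
  if (dicrotic > 0) {
    w <- w + 0.5 * dicrotic * cos(2 * phase + pi / 3)
    grid <- seq(0, 2 * pi, length.out = 721)
    ref <- 0.5 * cos(grid) + 0.5 * dicrotic * cos(2 * grid + pi / 3)
    w <- w / (max(ref) - min(ref))
  }
  w
}

#' Render one synthetic camera frame
#'
#' Draws the pinhole projection as a centred disc whose diameter is linear in
#' spring compression (`d_min` at rest, `d_max` at full travel). In-disc
#' intensity is `skin_baseline - amplitude * ppg_waveform(phase)` where the
#' amplitude comes from [envelope_amplitude()] at the contact pressure
#' implied by the compression; pixels outside the disc sit at the dim
#' background level. Gaussian noise is added per pixel and the result is
#' rounded and clipped to 8-bit.
#'
#' @param compression Spring compression in mm.
#' @param phase Cardiac phase in radians.
#' @param subject A [virtual_subject()].
#' @param optics An [optics_model()].
#' @param spring A [spring_model()].
#' @param geom A [contact_geometry()].
#' @return Integer matrix (rows x cols) of grey levels 0--255.
#' @export
render_frame <- function(compression, phase, subject, optics = optics_model(),
                         spring = spring_model(), geom = contact_geometry()) {
  d <- disc_diameter(compression, optics, spring)
  if (d > min(optics$frame_shape)) {
    stop("projected disc exceeds the frame", call. = FALSE)
  }
  p <- pressure_from_force(force_from_compression(compression, spring), geom)
  amp <- envelope_amplitude(p, subject)
  val <- subject$skin_baseline - amp * ppg_waveform(phase)
  render_frame_core(val, d, optics, disc_dist2(optics$frame_shape))
}

# Squared distance of every pixel centre from the frame centre.
disc_dist2 <- function(shape) {
  cy <- (shape[1] + 1) / 2
  cx <- (shape[2] + 1) / 2
  outer((seq_len(shape[1]) - cy)^2, (seq_len(shape[2]) - cx)^2, "+")
}

render_frame_core <- function(val, d, optics, dist2) {
  nr <- optics$frame_shape[1]
  nc <- optics$frame_shape[2]
  f <- matrix(optics$background_level, nr, nc)
  f[dist2 <= (d / 2)^2] <- val
  if (optics$noise_sd > 0) f <- f + rnorm(nr * nc, 0, optics$noise_sd)
  matrix(as.integer(clip(round(f), 0, 255)), nr, nc)
}

# --- session materialization -------------------------------------------------
# Given the protocol machine's recorded windows (force-scale samples at known
# times), produce what the camera would deliver: either real frames or the
# "signal" equivalent (the in-disc mean the imaging stage would extract, with
# noise sd scaled down by the square root of the disc pixel count).

materialize_levels <- function(windows, subject, optics, spring, geom,
                               frame_rate, mode) {
  omega <- 2 * pi * subject$heart_rate / 60
  frames <- list()
  frame_level <- integer(0)
  levels <- vector("list", length(windows))
  dist2 <- disc_dist2(optics$frame_shape)
  for (i in seq_along(windows)) {
    w <- windows[[i]]
    x <- w$scale / 100 * spring$max_travel
    if (mode == "frames") {
      p <- pressure_from_force(force_from_compression(x, spring), geom)
      vals <- subject$skin_baseline -
        envelope_amplitude(p, subject) * ppg_waveform(omega * w$t)
      ds <- disc_diameter(x, optics, spring)
      idx0 <- length(frames)
      for (j in seq_along(w$t)) {
        frames[[idx0 + j]] <- render_frame_core(vals[j], ds[j], optics,
                                                dist2)
      }
      frame_level <- c(frame_level, rep.int(w$level, length(w$t)))
      ppg <- NULL
      frame_idx <- idx0 + seq_along(w$t)
    } else {
      p <- pressure_from_force(force_from_compression(x, spring), geom)
      amp <- envelope_amplitude(p, subject)
      clean <- subject$skin_baseline - amp * ppg_waveform(omega * w$t)
      npx <- pmax(1, round(pi * (disc_diameter(x, optics, spring) / 2)^2))
      ppg <- clean + rnorm(length(w$t), 0, optics$noise_sd / sqrt(npx))
      frame_idx <- NULL
    }
    levels[[i]] <- list(level_index = w$level, target_scale = w$target,
                        attempts = w$attempts, t = w$t,
                        force_scale = w$scale, ppg = ppg,
                        frame_idx = frame_idx)
  }
  list(levels = levels, frames = if (mode == "frames") frames else NULL,
       frame_level = frame_level)
}

render_calibration <- function(subject, optics, spring, geom, frame_rate,
                               mode, n_each = 5) {
  if (mode != "frames") {
    return(list(size0 = optics$d_min, size100 = optics$d_max, frames = NULL))
  }
  omega <- 2 * pi * subject$heart_rate / 60
  t0 <- seq(0, by = 1 / frame_rate, length.out = n_each)
  f0 <- lapply(t0, function(t) render_frame(0, omega * t, subject, optics,
                                            spring, geom))
  f1 <- lapply(t0, function(t) render_frame(spring$max_travel, omega * t,
                                            subject, optics, spring, geom))
  list(size0 = optics$d_min, size100 = optics$d_max,
       frames = list(at_0pct = f0, at_100pct = f1))
}

#' Synthesize one complete measurement session
#'
#' Runs an ideal simulated user (instant force acquisition, no tremor, no
#' band violations) through the guidance protocol and renders the recorded
#' 5-s windows of every force level, either as 8-bit frame stacks
#' (`mode = "frames"`) or as the equivalent extracted force/PPG series
#' (`mode = "signal"`). Deterministic for a fixed seed.
#'
#' @param subject A [virtual_subject()].
#' @param optics An [optics_model()].
#' @param protocol A [protocol_config()].
#' @param spring,geom Mechanics models.
#' @param frame_rate Sampling/frame rate in Hz (>= 20).
#' @param seed Integer seed.
#' @param mode `"frames"` or `"signal"`.
#' @return A `session_recording`; see [run_session()].
#' @export
synth_session <- function(subject, optics = optics_model(),
                          protocol = protocol_config(),
                          spring = spring_model(), geom = contact_geometry(),
                          frame_rate = 30, seed = 1,
                          mode = c("signal", "frames")) {
  run_session(subject, user = user_model(), optics = optics,
              protocol = protocol, spring = spring, geom = geom,
              frame_rate = frame_rate, seed = seed, mode = mode)
}

#' Synthesize a cohort of subjects with sessions and ground truth
#'
#' Draws `n` subjects from a [cohort_population()] and simulates one session
#' each. Optionally forces a fixed number of subjects to be pulseless
#' (perfusion gain below the detection floor) and a fixed number to have a
#' reference pulse pressure above 80 mmHg, mirroring screening edge cases;
#' all remaining subjects are drawn with pulse pressure inside the
#' population's retained range.
#'
#' @param n Number of subjects (>= 1).
#' @param seed Integer master seed; per-subject seeds are derived from it.
#' @param population A [cohort_population()].
#' @param optics,protocol,spring,geom Forward-model configuration.
#' @param frame_rate Sampling rate in Hz.
#' @param mode `"signal"` or `"frames"`.
#' @param n_pulseless Number of subjects forced to have no detectable pulse.
#' @param n_high_pp Number of subjects forced to pulse pressure > 80 mmHg.
#' @param user A [user_model()] applied to every session.
#' @return A list of class `bp_cohort`: each element has `$subject`
#'   (ground truth), `$recording` (the session), and `$subject_id`.
#' @examples
#' coh <- synth_cohort(2, seed = 1, optics = optics_model(8, 24, c(32, 32)))
#' length(coh)
#' @export
synth_cohort <- function(n, seed = 1, population = cohort_population(),
                         optics = optics_model(),
                         protocol = protocol_config(),
                         spring = spring_model(), geom = contact_geometry(),
                         frame_rate = 30, mode = c("signal", "frames"),
                         n_pulseless = 0, n_high_pp = 0,
                         user = user_model()) {
  mode <- match.arg(mode)
  stopifnot(n >= 1, n_pulseless + n_high_pp <= n)
  subjects <- with_seed(seed, {
    special <- sample.int(n, n_pulseless + n_high_pp)
    pulseless <- special[seq_len(n_pulseless)]
    high_pp <- setdiff(special, pulseless)
    lapply(seq_len(n), function(i) {
      s <- draw_subject(population)
      if (i %in% high_pp) {
        sbp <- runif(1, 150, 170)
        dbp <- sbp - runif(1, 82, 95)
        s <- virtual_subject(sbp, dbp, s$heart_rate, s$perfusion_gain,
                             s$envelope_width, s$skin_baseline)
      }
      if (i %in% pulseless) {
        s <- virtual_subject(s$sbp_true, s$dbp_true, s$heart_rate,
                             population$pulseless_gain, s$envelope_width,
                             s$skin_baseline)
      }
      s
    })
  })
  out <- lapply(seq_len(n), function(i) {
    rec <- run_session(subjects[[i]], user = user, optics = optics,
                       protocol = protocol, spring = spring, geom = geom,
                       frame_rate = frame_rate,
                       seed = child_seed(seed, i), mode = mode)
    list(subject_id = sprintf("S%03d", i), subject = subjects[[i]],
         recording = rec)
  })
  structure(out, class = "bp_cohort", seed = seed)
}

#' Ground-truth manifest of a synthetic cohort
#'
#' @param cohort A `bp_cohort` from [synth_cohort()].
#' @return A data frame with one row per subject: id, reference SBP/DBP/MBP,
#'   heart rate, perfusion gain, envelope width.
#' @export
cohort_manifest <- function(cohort) {
  stopifnot(inherits(cohort, "bp_cohort"))
  do.call(rbind, lapply(cohort, function(el) {
    s <- el$subject
    data.frame(subject_id = el$subject_id, sbp_ref = s$sbp_true,
               dbp_ref = s$dbp_true, mbp_ref = s$mbp_true,
               heart_rate = s$heart_rate, perfusion_gain = s$perfusion_gain,
               envelope_width = s$envelope_width)
  }))
}
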