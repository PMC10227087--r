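# Guidance protocol: target force levels, the RED/YELLOW/GREEN state
# machine, and a simulated user driving it.
#
# Semantics mirror the measurement app: the indicator is RED until the force
# enters the +/-tolerance band around the current target (-> YELLOW), turns
# GREEN after hold_s continuously in band, and the level completes after a
# further record_s in band; any out-of-band sample while YELLOW or GREEN
# discards the attempt and returns to RED. After n_levels completed levels
# the session terminates. Only the final record_s window of each level is
# recorded.

#' Configuration of the guided force protocol
#'
#' Defaults encode the 20-level protocol: targets equally divided from 5 to
#' 95% of the force scale, +/-2 percentage-point tolerance, 2 s hold before
#' recording, 5 s recorded per level (7 s per level, 140 s minimum total).
#'
#' @param n_levels Number of force levels (>= 2).
#' @param scale_lo,scale_hi First and last target in % of the force scale.
#' @param tolerance Band half-width in absolute percentage points.
#' @param hold_s Continuous in-band time before recording starts, s.
#' @param record_s Recorded duration per level, s.
#' @return An object of class `protocol_config`.
#' @export
protocol_config <- function(n_levels = 20, scale_lo = 5, scale_hi = 95,
                            tolerance = 2, hold_s = 2, record_s = 5) {
  stopifnot(n_levels >= 2, scale_lo < scale_hi, tolerance > 0,
            hold_s >= 0, record_s > 0)
  structure(list(n_levels = as.integer(n_levels), scale_lo = scale_lo,
                 scale_hi = scale_hi, tolerance = tolerance,
                 hold_s = hold_s, record_s = record_s),
            class = "protocol_config")
}

#' Target force-scale levels
#'
#' `n_levels` values equally spaced from `scale_lo` to `scale_hi`, endpoints
#' inclusive (spacing `(scale_hi - scale_lo) / (n_levels - 1)`).
#'
#' @param cfg A [protocol_config()].
#' @return Numeric vector of target scales in %, strictly increasing.
#' @examples
#' target_levels(protocol_config())[c(1, 20)]  # 5, 95
#' @export
target_levels <- function(cfg = protocol_config()) {
  stopifnot(inherits(cfg, "protocol_config"))
  seq(cfg$scale_lo, cfg$scale_hi, length.out = cfg$n_levels)
}

#' Initial state of the protocol machine
#'
#' @param cfg A [protocol_config()].
#' @return A state list consumed and returned by [advance_state()].
#' @export
protocol_init <- function(cfg = protocol_config()) {
  list(cfg = cfg, targets = target_levels(cfg), level = 1L, phase = "RED",
       t_yellow = NA_real_, t_last = -Inf, attempts = 1L, discarded_s = 0,
       completed = list(), terminated = FALSE)
}

#' Advance the protocol state machine by one force sample
#'
#' Completion is evaluated from elapsed time before the band test, so a level
#' completes exactly at `t_yellow + hold_s + record_s` even if the sample that
#' reveals the completion already sits at the next target. Out-of-band
#' samples while YELLOW/GREEN discard the attempt (its in-band time is
#' accumulated as discarded time) and return to RED.
#'
#' @param state State from [protocol_init()] or a previous call.
#' @param force_scale Current force-scale sample in %.
#' @param t Sample timestamp in s; must be strictly greater than the previous
#'   one.
#' @return The updated state. `state$terminated` becomes `TRUE` once all
#'   levels are complete; `state$completed` lists per-level records with the
#'   recording window `[t_yellow + hold_s, t_complete]` and attempt counts.
#' @export
advance_state <- function(state, force_scale, t) {
  if (!is.finite(t) || t <= state$t_last) {
    stop("timestamps must be strictly increasing", call. = FALSE)
  }
  state$t_last <- t
  if (state$terminated) return(state)
  cfg <- state$cfg
  total <- cfg$hold_s + cfg$record_s
  if (state$phase != "RED" && t - state$t_yellow >= total) {
    state$completed[[length(state$completed) + 1L]] <- list(
      level = state$level, target = state$targets[state$level],
      t_yellow = state$t_yellow, t_record = state$t_yellow + cfg$hold_s,
      t_complete = state$t_yellow + total, attempts = state$attempts)
    state$level <- state$level + 1L
    state$phase <- "RED"
    state$t_yellow <- NA_real_
    state$attempts <- 1L
    if (state$level > cfg$n_levels) {
      state$terminated <- TRUE
      return(state)
    }
  }
  tgt <- state$targets[state$level]
  in_band <- abs(force_scale - tgt) <= cfg$tolerance
  if (state$phase == "RED") {
    if (in_band) {
      state$phase <- "YELLOW"
      state$t_yellow <- t
    }
  } else if (!in_band) {
    state$discarded_s <- state$discarded_s + (t - state$t_yellow)
    state$phase <- "RED"
    state$t_yellow <- NA_real_
    state$attempts <- state$attempts + 1L
  } else if (t - state$t_yellow >= cfg$hold_s) {
    state$phase <- "GREEN"
  }
  state
}

#' Replay a scripted force trace through the machine
#'
#' @param cfg A [protocol_config()].
#' @param t,force_scale Equal-length vectors of timestamps and samples.
#' @return The final state.
#' @export
replay_trace <- function(cfg, t, force_scale) {
  stopifnot(length(t) == length(force_scale))
  state <- protocol_init(cfg)
  for (i in seq_along(t)) state <- advance_state(state, force_scale[i], t[i])
  state
}

#' Active measurement time of a session
#'
#' Accumulated in-band (YELLOW + GREEN) time: each completed level
#' contributes exactly `hold_s + record_s` and each discarded attempt the
#' time from band entry to the violation. An ideal user therefore takes
#' `n_levels * (hold_s + record_s)` s — 140 s at the defaults.
#'
#' @param state A protocol state.
#' @return Time in s.
#' @export
session_time <- function(state) {
  total <- state$cfg$hold_s + state$cfg$record_s
  length(state$completed) * total + state$discarded_s
}

#' Simulated user behaviour
#'
#' @param acquisition_delay Time in s the user needs to reach each new target
#'   band (force is out of band meanwhile).
#' @param tremor_sd Standard deviation (percentage points) of the force
#'   tremor while holding a target; tremor is kept inside the tolerance band
#'   so violations occur only via `violation_rate`.
#' @param violation_rate Probability that a level's first attempt contains
#'   one out-of-band excursion (forcing a restart of that level).
#' @param max_attempts Attempts allowed per level before the session is
#'   marked incomplete.
#' @return An object of class `user_model`.
#' @export
user_model <- function(acquisition_delay = 0, tremor_sd = 0,
                       violation_rate = 0, max_attempts = 5L) {
  stopifnot(acquisition_delay >= 0, tremor_sd >= 0,
            violation_rate >= 0, violation_rate <= 1, max_attempts >= 1)
  structure(list(acquisition_delay = acquisition_delay, tremor_sd = tremor_sd,
                 violation_rate = violation_rate,
                 max_attempts = as.integer(max_attempts)),
            class = "user_model")
}

#' Run one simulated measurement session
#'
#' Co-simulates a [user_model()] against the protocol machine at the given
#' sampling rate, then renders the recorded windows with the forward model.
#' Deterministic for a fixed seed.
#'
#' @param subject A [virtual_subject()].
#' @param user A [user_model()].
#' @param optics An [optics_model()].
#' @param protocol A [protocol_config()].
#' @param spring,geom Mechanics models.
#' @param frame_rate Sampling/frame rate in Hz.
#' @param seed Integer seed.
#' @param mode `"signal"` (extracted-equivalent force/PPG series) or
#'   `"frames"` (8-bit frame stacks).
#' @return An object of class `session_recording` with elements `levels`
#'   (per-level records: timestamps, force-scale and PPG series or frame
#'   indices, attempts), `frames`/`frame_level` (frame mode), `calibration`
#'   (0%/100% disc sizes, with frames in frame mode), the ground-truth
#'   `subject`, the configuration blocks, `complete`, `measurement_s` and
#'   `wall_s`.
#' @export
run_session <- function(subject, user = user_model(),
                        optics = optics_model(),
                        protocol = protocol_config(),
                        spring = spring_model(), geom = contact_geometry(),
                        frame_rate = 30, seed = 1,
                        mode = c("signal", "frames")) {
  mode <- match.arg(mode)
  stopifnot(inherits(subject, "virtual_subject"), frame_rate >= 20)
  cfg <- protocol
  with_seed(seed, {
    targets <- target_levels(cfg)
    dt <- 1 / frame_rate
    st <- protocol_init(cfg)
    cap <- ceiling(frame_rate * cfg$n_levels * user$max_attempts *
                     (cfg$hold_s + cfg$record_s +
                        user$acquisition_delay + 2)) + 60L * frame_rate
    t_all <- numeric(cap)
    s_all <- numeric(cap)
    i <- 0L
    cur_level <- 0L
    cur_attempt <- 0L
    level_start <- 0
    viol_now <- FALSE
    viol_at <- Inf
    incomplete <- FALSE
    while (!st$terminated) {
      t <- i * dt
      if (st$level != cur_level || st$attempts != cur_attempt) {
        if (st$level != cur_level) level_start <- t
        cur_level <- st$level
        cur_attempt <- st$attempts
        # each attempt may contain one scheduled out-of-band excursion
        viol_now <- runif(1) < user$violation_rate
        viol_at <- runif(1, 0.5, cfg$hold_s + cfg$record_s - 0.5)
      }
      tgt <- targets[cur_level]
      if (t - level_start < user$acquisition_delay) {
        scale <- clip(tgt - 3 * cfg$tolerance - 2, 0, 100)
      } else if (user$tremor_sd > 0) {
        scale <- tgt + clip(rnorm(1, 0, user$tremor_sd),
                            -0.95 * cfg$tolerance, 0.95 * cfg$tolerance)
      } else {
        scale <- tgt
      }
      if (viol_now && st$phase != "RED" && t - st$t_yellow >= viol_at) {
        scale <- tgt + 2 * cfg$tolerance + 1
      }
      i <- i + 1L
      t_all[i] <- t
      s_all[i] <- scale
      st <- advance_state(st, scale, t)
      if (st$attempts > user$max_attempts || i >= cap) {
        incomplete <- TRUE
        break
      }
    }
    t_all <- t_all[seq_len(i)]
    s_all <- s_all[seq_len(i)]
    windows <- lapply(st$completed, function(cp) {
      # half-open window [t_record, t_complete): exactly record_s of data,
      # i.e. record_s * frame_rate samples on the sampling grid
      sel <- which(t_all >= cp$t_record - 1e-9 &
                     t_all < cp$t_complete - 1e-9)
      list(level = cp$level, target = cp$target, attempts = cp$attempts,
           t = t_all[sel], scale = s_all[sel])
    })
    mat <- materialize_levels(windows, subject, optics, spring, geom,
                              frame_rate, mode)
    cal <- render_calibration(subject, optics, spring, geom, frame_rate,
                              mode)
    structure(list(
      mode = mode, frame_rate = frame_rate, seed = seed,
      subject = subject, optics = optics, spring = spring, geom = geom,
      protocol = cfg, levels = mat$levels, frames = mat$frames,
      frame_level = mat$frame_level, calibration = cal,
      complete = !incomplete, measurement_s = session_time(st),
      wall_s = if (length(st$completed)) {
        st$completed[[length(st$completed)]]$t_complete
      } else NA_real_,
      attempts = vapply(st$completed, `[[`, integer(1), "attempts")),
      class = "session_recording")
  })
}

#' @export
print.session_recording <- function(x, ...) {
  cat(sprintf(
    "<session_recording> %s mode, %d/%d levels, %.1f s measurement%s\n",
    x$mode, length(x$levels), x$protocol$n_levels, x$measurement_s,
    if (x$complete) "" else " [incomplete]"))
  invisible(x)
}
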