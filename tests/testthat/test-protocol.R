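# Guidance state machine: level targets, hold/record phases, violations,
# timing, and the simulated user.

test_that("target levels are equally divided, endpoints inclusive", {
  tg <- target_levels(protocol_config())
  expect_length(tg, 20)
  expect_equal(tg[1], 5)
  expect_equal(tg[20], 95)
  expect_equal(unique(round(diff(tg), 10)), round(90 / 19, 10))
  expect_true(all(diff(tg) > 0))
  expect_equal(target_levels(protocol_config(n_levels = 2)), c(5, 95))
})

# Scripted ideal trace: per level, samples at the level's target on the
# sampling grid; each level block spans [7*(i-1), 7*i).
ideal_trace <- function(cfg = protocol_config(), fs = 30) {
  tg <- target_levels(cfg)
  per <- cfg$hold_s + cfg$record_s
  t <- seq(0, cfg$n_levels * per, by = 1 / fs)
  lvl <- pmin(floor(t / per) + 1, cfg$n_levels)
  list(t = t, scale = tg[lvl])
}

test_that("an ideal user completes the session in exactly 140 s", {
  cfg <- protocol_config()
  tr <- ideal_trace(cfg)
  st <- replay_trace(cfg, tr$t, tr$scale)
  expect_true(st$terminated)
  expect_length(st$completed, 20)
  expect_equal(session_time(st), 140)
  expect_equal(st$completed[[20]]$t_complete, 140)
  # every completed level holds exactly hold+record seconds
  for (cp in st$completed) {
    expect_equal(cp$t_complete - cp$t_yellow, 7)
  }
})

test_that("a band violation discards the level and adds its elapsed time", {
  cfg <- protocol_config()
  fs <- 30
  dt <- 1 / fs
  tg <- target_levels(cfg)
  # per-level in-band blocks with a small slack after each completion; at
  # level 5 one out-of-band sample 1 s into GREEN (3 s after band entry)
  t <- numeric(0)
  s <- numeric(0)
  cur <- 0
  block <- function(t0, dur, scale) {
    tt <- seq(t0, t0 + dur - dt / 2, by = dt)
    list(t = tt, s = rep(scale, length(tt)))
  }
  for (i in seq_len(cfg$n_levels)) {
    if (i == 5) {
      b1 <- block(cur, cfg$hold_s + 1, tg[i])           # yellow then green
      t <- c(t, b1$t, cur + cfg$hold_s + 1)             # violation sample
      s <- c(s, b1$s, tg[i] + cfg$tolerance + 3)
      cur <- cur + cfg$hold_s + 1 + dt
    }
    b <- block(cur, cfg$hold_s + cfg$record_s + 5 * dt, tg[i])
    t <- c(t, b$t)
    s <- c(s, b$s)
    cur <- max(b$t) + dt
  }
  st <- replay_trace(cfg, t, s)
  expect_true(st$terminated)
  expect_equal(session_time(st), 140 + cfg$hold_s + 1)
  expect_equal(st$completed[[5]]$attempts, 2)
  for (i in setdiff(seq_len(cfg$n_levels), 5)) {
    expect_equal(st$completed[[i]]$attempts, 1)
  }
})

test_that("a user who never enters the band never progresses", {
  cfg <- protocol_config()
  t <- seq(0, 30, by = 1 / 30)
  st <- replay_trace(cfg, t, rep(0, length(t)))  # target 5 +/- 2, force 0
  expect_equal(st$phase, "RED")
  expect_length(st$completed, 0)
  expect_equal(session_time(st), 0)
})

test_that("timestamps must be strictly increasing", {
  st <- protocol_init(protocol_config())
  st <- advance_state(st, 5, 0)
  expect_error(advance_state(st, 5, 0), "increasing")
  expect_error(advance_state(st, 5, -1), "increasing")
})

test_that("simulated sessions honour the recording contract", {
  cfg <- protocol_config()
  rec <- run_session(test_subject(), user = user_model(tremor_sd = 0.5),
                     seed = 31, mode = "signal")
  expect_true(rec$complete)
  expect_length(rec$levels, cfg$n_levels)
  tg <- target_levels(cfg)
  for (lv in rec$levels) {
    # exactly record_s of data at the sampling grid
    expect_equal(length(lv$t), cfg$record_s * rec$frame_rate)
    # no recorded sample outside the tolerance band
    expect_true(all(abs(lv$force_scale - tg[lv$level_index]) <=
                      cfg$tolerance + 1e-9))
  }
  expect_equal(rec$measurement_s, 140)
})

test_that("delays and violations stretch the session; rate 1 aborts it", {
  slow <- run_session(test_subject(),
                      user = user_model(acquisition_delay = 1,
                                        violation_rate = 0.5),
                      seed = 17, mode = "signal")
  expect_true(slow$complete)
  expect_gt(slow$measurement_s, 140)
  expect_true(any(slow$attempts > 1))
  bad <- run_session(test_subject(), user = user_model(violation_rate = 1),
                     seed = 17, mode = "signal")
  expect_false(bad$complete)
})

test_that("identical seeds replay identical sessions", {
  u <- user_model(acquisition_delay = 0.5, tremor_sd = 0.8,
                  violation_rate = 0.3)
  a <- run_session(test_subject(), user = u, seed = 77, mode = "signal")
  b <- run_session(test_subject(), user = u, seed = 77, mode = "signal")
  expect_identical(a$levels, b$levels)
  expect_identical(a$measurement_s, b$measurement_s)
})
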