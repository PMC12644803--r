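# Game rules: spawning, movement cap, hover collection, payoffs, respawn.

test_that("initialization is deterministic under a fixed seed", {
  s1 <- init_session(cfg_std(), 7)
  s2 <- init_session(cfg_std(), 7)
  expect_identical(s1, s2)
  s3 <- init_session(cfg_std(), 8)
  expect_false(identical(s3$targets, s1$targets))
})

test_that("spawns are uniform on the admissible region and never overlap", {
  cfg <- cfg_std()
  n <- 3000
  singles <- matrix(NA_real_, n, 2)
  mind <- numeric(n)
  agent_x <- numeric(n)
  for (i in seq_len(n)) {
    st <- init_session(cfg, i)
    singles[i, ] <- st$targets[1, ]
    mind[i] <- min(dist(st$targets))
    agent_x[i] <- st$pos[1, 1]
  }
  # the single target is placed first, so its marginal is exactly uniform
  # on the radius-inset interval
  r <- cfg$target_radius
  expect_gt(stats::ks.test(singles[, 1], "punif", r, cfg$field_side - r)$p.value, 0.01)
  expect_gt(stats::ks.test(singles[, 2], "punif", r, cfg$field_side - r)$p.value, 0.01)
  expect_gt(stats::ks.test(agent_x, "punif", 0, cfg$field_side)$p.value, 0.01)
  # centre distances all exceed the target diameter (5 cm)
  expect_true(all(mind > cfg$target_diameter))
})

test_that("commanded speed above the cap is clipped to 42.6 cm/s", {
  cfg <- cfg_std()
  st <- init_session(cfg, 1)
  st$pos[] <- c(1, 1, 1, 50)   # away from targets
  st$targets[] <- 25           # park all targets at the field centre-ish
  st$targets[2, ] <- c(30, 30); st$targets[3, ] <- c(40, 40)
  p0 <- st$pos[1, ]
  vel <- rbind(c(60, 0), c(0, 0))
  for (k in seq_len(cfg$tick_rate)) st <- step_game(st, vel)
  moved <- sqrt(sum((st$pos[1, ] - p0)^2))
  expect_equal(moved, cfg$max_speed, tolerance = 1e-9)
  # a commanded speed below the cap is not altered
  st2 <- init_session(cfg, 1)
  st2$pos[] <- c(1, 1, 1, 50)
  p0 <- st2$pos[1, ]
  st2 <- step_game(st2, rbind(c(30, 0), c(0, 0)))
  expect_equal(sqrt(sum((st2$pos[1, ] - p0)^2)), 30 * cfg$dt, tolerance = 1e-9)
})

test_that("leaving a target before completion resets hover progress", {
  cfg <- cfg_std()
  st <- init_session(cfg, 3)
  # put agent A on the single target
  st$pos[1, ] <- st$targets[1, ]
  st$pos[2, ] <- c(0, 0)
  zero <- matrix(0, 2, 2)
  for (k in seq_len(as.integer(0.5 * cfg$tick_rate)))
    st <- step_game(st, zero)
  expect_gt(st$progress[1], 0.4)
  # one tick away resets
  st <- step_game(st, rbind(c(cfg$max_speed, 0), c(0, 0)) * 20)  # clipped, moves 0.355 cm
  # move far enough to leave the 2.5 cm radius: step away repeatedly
  for (k in 1:10) st <- step_game(st, rbind(c(cfg$max_speed, 0), c(0, 0)))
  expect_identical(unname(st$progress[1]), 0)
  expect_true(is.na(st$single_claimant))
})

test_that("zero commanded velocity changes nothing but the clock", {
  st <- init_session(cfg_std(), 5)
  st2 <- step_game(st, matrix(0, 2, 2))
  expect_equal(st2$pos, st$pos)
  expect_equal(st2$targets, st$targets)
  expect_equal(st2$time, st$time + cfg_std()$dt)
})

test_that("collection pays 7/0 for singles, 5/2 for joints, and respawns only the collected target", {
  cfg <- cfg_std()
  st <- init_session(cfg, 11)
  zero <- matrix(0, 2, 2)

  # jointA: both agents on it
  st$pos[1, ] <- st$targets[2, ]; st$pos[2, ] <- st$targets[2, ]
  old <- st$targets
  for (k in seq_len(cfg$hover_ticks + 1L)) st <- step_game(st, zero)
  expect_identical(completed_target(st), 2L)
  res <- resolve_collection(st)
  expect_equal(res$event$payoff_a, cfg$payoff_joint_major)
  expect_equal(res$event$payoff_b, cfg$payoff_joint_minor)
  expect_equal(res$event$collector, "both")
  # the other two targets are untouched; the collected one moved
  expect_equal(res$state$targets[c(1, 3), ], old[c(1, 3), ])
  expect_false(all(res$state$targets[2, ] == old[2, ]))
  expect_true(min(dist(res$state$targets)) > cfg$target_diameter)

  # single claimed by B
  st <- res$state
  st$pos[1, ] <- c(0, 0); st$pos[2, ] <- st$targets[1, ]
  for (k in seq_len(cfg$hover_ticks + 1L)) st <- step_game(st, zero)
  res2 <- resolve_collection(st)
  expect_equal(res2$event$payoff_a, 0)
  expect_equal(res2$event$payoff_b, cfg$payoff_single)
  expect_equal(res2$event$collector, "B")
  expect_equal(unname(res2$state$payoffs),
               c(cfg$payoff_joint_major, cfg$payoff_joint_minor + cfg$payoff_single))
})

test_that("a joint target needs both agents; one alone accrues nothing", {
  cfg <- cfg_std()
  st <- init_session(cfg, 13)
  st$pos[1, ] <- st$targets[2, ]; st$pos[2, ] <- c(1, 1)
  zero <- matrix(0, 2, 2)
  for (k in 1:60) st <- step_game(st, zero)
  expect_identical(unname(st$progress[2]), 0)
})

test_that("invalid inputs are rejected", {
  cfg <- cfg_std()
  st <- init_session(cfg, 1)
  expect_error(step_game(st, matrix(c(NA, 0, 0, 0), 2, 2)), "non-finite")
  expect_error(step_game(st, matrix(0, 2, 2), dt = 0.5), "tick_rate")
  expect_error(resolve_collection(st), "no completed target")
  expect_error(game_config(field_side = 8), "too small")
  expect_error(game_config(payoff_joint_major = 6), "joint payoffs")
  expect_error(game_config(hover_time = 0.9995), "integer number of ticks")
})

test_that("payoffs are conserved and every event carries the same joint payoff", {
  ses <- mixed_session()
  ev <- ses$events
  expect_true(all(ev$payoff_a_cents + ev$payoff_b_cents == 7))
  expect_equal(sum(ev$payoff_a_cents) + sum(ev$payoff_b_cents), 7 * nrow(ev))
})

test_that("the speed bound holds on every simulated tick", {
  ses <- mixed_session()
  cfg <- ses$config
  p <- ses$positions
  da <- sqrt(diff(p$ax_cm)^2 + diff(p$ay_cm)^2)
  db <- sqrt(diff(p$bx_cm)^2 + diff(p$by_cm)^2)
  expect_true(all(da / cfg$dt <= cfg$max_speed + 1e-9))
  expect_true(all(db / cfg$dt <= cfg$max_speed + 1e-9))
})

test_that("replaying a simulated velocity stream through the tick engine reproduces the session", {
  cfg <- cfg_std()
  p <- policy_params(w = 0.5, speed_factor = 0.9, reaction_delay = 0.1,
                     reaction_jitter = 0.2, miscoord_p = 0.1)
  ses <- simulate_dyad(cfg, p, p, 40, seed = 123)
  pos <- as.matrix(ses$positions[, c("ax_cm", "ay_cm", "bx_cm", "by_cm")])
  ev <- ses$events

  st <- init_session(cfg, 1)
  st$pos[1, ] <- pos[1, 1:2]; st$pos[2, ] <- pos[1, 3:4]
  st$targets[1, ] <- c(ev$single_x_cm[1], ev$single_y_cm[1])
  st$targets[2, ] <- c(ev$jointA_x_cm[1], ev$jointA_y_cm[1])
  st$targets[3, ] <- c(ev$jointB_x_cm[1], ev$jointB_y_cm[1])

  k <- 1L
  for (t in seq_len(nrow(pos) - 1L)) {
    vel <- rbind(pos[t + 1L, 1:2] - pos[t, 1:2],
                 pos[t + 1L, 3:4] - pos[t, 3:4]) / cfg$dt
    st <- step_game(st, vel)
    if (length(completed_target(st)) > 0L) {
      res <- resolve_collection(st)
      expect_equal(res$event$kind, ev$target_kind[k])
      expect_equal(res$event$t_end, ev$t_end_s[k], tolerance = 1e-9)
      expect_equal(res$event$collector, ev$collector[k])
      expect_equal(res$event$payoff_a, ev$payoff_a_cents[k])
      st <- res$state
      if (k < nrow(ev)) {
        # align the engine's random respawn with the logged layout
        st$targets[1, ] <- c(ev$single_x_cm[k + 1L], ev$single_y_cm[k + 1L])
        st$targets[2, ] <- c(ev$jointA_x_cm[k + 1L], ev$jointA_y_cm[k + 1L])
        st$targets[3, ] <- c(ev$jointB_x_cm[k + 1L], ev$jointB_y_cm[k + 1L])
      }
      k <- k + 1L
    }
  }
  expect_equal(k - 1L, nrow(ev))
  expect_equal(unname(st$payoffs),
               c(sum(ev$payoff_a_cents), sum(ev$payoff_b_cents)))
})
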