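# Payoff decomposition: limiting kinematics, the ratio-of-averages payoff
# approximation, and the length-component identity.

test_that("idealized straight-line play gives zero curvature and the set speed", {
  ses <- turntaking_session()
  cy <- segment_cycles(ses)
  kin <- cycle_kinematics(cy)
  moved <- kin$limiting_length_cm > 1
  expect_true(all(kin$curvature_cm[moved] < 0.51))
  expect_equal(median(kin$mean_speed_cm_s[moved]), ses$config$max_speed,
               tolerance = 1e-6)
})

test_that("the last-entering agent limits joint collections", {
  pa <- policy_params(w = 0, turn_taking = TRUE, reaction_delay = 0,
                      reaction_jitter = 0, hover_drift = 0)
  pb <- policy_params(w = 0, turn_taking = TRUE, reaction_delay = 0.4,
                      reaction_jitter = 0, hover_drift = 0)
  ses <- simulate_dyad(cfg_std(), pa, pb, 100, seed = 19)
  kin <- cycle_kinematics(segment_cycles(ses))
  expect_true(mean(kin$limiting[-1] == "B") > 0.95)
})

test_that("the payoff approximation is near-exact in the idealized limit", {
  ses <- turntaking_session()
  cy <- segment_cycles(ses)
  pay <- suppressWarnings(payoff_approximation(cycle_kinematics(cy), cy))
  expect_lt(abs(pay$estimated_rate - pay$actual_rate) / pay$actual_rate, 0.01)
  # the engine's payoff rate is exactly joint payoff x events / time
  total_t <- cy$t_end_s[nrow(cy)] - cy$t_start_s[1]
  expect_equal(pay$actual_rate, 7 * nrow(cy) / total_t)
})

test_that("halving the speed roughly doubles travel time at fixed paths", {
  mk <- function(sf) {
    p <- policy_params(w = 0.5, speed_factor = sf, reaction_delay = 0,
                       reaction_jitter = 0, hover_drift = 0)
    ses <- simulate_dyad(cfg_std(), p, p, 200, seed = 29)
    cy <- segment_cycles(ses)
    pay <- suppressWarnings(payoff_approximation(cycle_kinematics(cy), cy))
    pay$estimated_duration_s - ses$config$hover_time
  }
  expect_equal(mk(0.5) / mk(1), 2, tolerance = 0.1)
})

test_that("the length decomposition identity is exact", {
  for (fix in list(mixed_cycles(), invite_cycles())) {
    kin <- cycle_kinematics(fix)
    dec <- length_decomposition(kin)
    expect_equal(dec$mean_limiting_cm,
                 dec$straight_cm - dec$placement_cm + dec$curvature_cm,
                 tolerance = 1e-9)
  }
})

test_that("placement reduction is near zero without placement and positive with it", {
  kin0 <- cycle_kinematics(mixed_cycles())
  expect_lt(abs(length_decomposition(kin0)$placement_cm), 2)

  cfg <- cfg_std()
  p <- policy_params(w = 0.75, placement_mode = "advantageous",
                     reaction_jitter = 0.2)
  ses <- simulate_dyad(cfg, p, p, 250, seed = 37)
  kin1 <- cycle_kinematics(segment_cycles(ses))
  expect_gt(length_decomposition(kin1)$placement_cm, 1)
})

test_that("mean speed stays flat across the strategy spectrum at fixed speed factor", {
  cfg <- cfg_std()
  sp <- sapply(c(0.2, 0.5, 0.8), function(w) {
    p <- policy_params(w = w, speed_factor = 0.9, reaction_delay = 0,
                       reaction_jitter = 0, hover_drift = 0)
    ses <- simulate_dyad(cfg, p, p, 200, seed = 41)
    kin <- cycle_kinematics(segment_cycles(ses))
    median(kin$mean_speed_cm_s[kin$limiting_length_cm > 1])
  })
  expect_lt(diff(range(sp)) / mean(sp), 0.02)
})
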