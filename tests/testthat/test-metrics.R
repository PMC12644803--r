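# Cycle segmentation, FST time courses, convergence and grouping.

test_that("segmentation yields one contiguous cycle per event", {
  ses <- mixed_session()
  cy <- segment_cycles(ses)
  expect_equal(nrow(cy), nrow(ses$events))
  expect_equal(cy$t_start_s[-1], cy$t_end_s[-nrow(cy)])
  # start positions equal the positions at the previous collection's end
  idx <- cy$tick_start + 1L
  expect_equal(cy$ax_cm, ses$positions$ax_cm[idx])
  expect_equal(cy$by_cm, ses$positions$by_cm[idx])
  # previous outcomes line up with the event stream
  expect_equal(cy$prev1_kind[-1], ses$events$target_kind[-nrow(cy)])
  expect_true(is.na(cy$prev1_kind[1]) && is.na(cy$prev2_kind[2]))
})

test_that("an empty event list produces an empty cycle set", {
  ses <- mixed_session()
  ses$events <- ses$events[0, ]
  expect_equal(nrow(segment_cycles(ses)), 0L)
})

test_that("non-monotone events are rejected", {
  ses <- mixed_session()
  ses$events$t_end_s[2] <- ses$events$t_end_s[5]
  expect_error(segment_cycles(ses), "increasing")
})

test_that("FST time course counts events in the trailing window", {
  # 20 singles then 40 joints, one event per second: at the last event a
  # 60-s window holds all 60 events -> FST 1/3
  cy <- data.frame(
    t_end_s = 1:60,
    target_kind = c(rep("single", 20), rep("jointA", 40))
  )
  tc <- fst_timecourse(cy, window = 60)
  expect_equal(tc$fst[60], 1 / 3)
  expect_equal(tc$n_events[60], 60)
  # all-single log: constant 1
  cy2 <- data.frame(t_end_s = 1:30, target_kind = "single")
  expect_true(all(fst_timecourse(cy2, 10)$fst == 1))
  # alternating kinds: 0.5 away from the edges
  cy3 <- data.frame(t_end_s = 1:100,
                    target_kind = rep(c("single", "jointB"), 50))
  tc3 <- fst_timecourse(cy3, window = 20)
  expect_true(all(abs(tc3$fst[21:100] - 0.5) <= 0.026))
})

test_that("stable strategy, groups and convergence behave on constructed series", {
  mk <- function(kinds) data.frame(
    t_end_s = seq_along(kinds), target_kind = kinds,
    payoff_a_cents = 3.5, payoff_b_cents = 3.5)

  # constant cooperative series
  co <- mk(rep(c("single", rep("jointA", 19)), 60))  # FST 0.05
  s <- stable_strategy(co, analysis_start = 600, block_duration = 600)
  expect_equal(s$phi, 0.05, tolerance = 0.01)
  expect_equal(s$group, "cooperative")
  # constant strategy: converged from the start (up to the thin first
  # windows, which hold only a handful of events)
  expect_lt(s$convergence_s, 10)
  expect_false(s$block_inconsistent)

  # constant competitive series
  cp <- mk(rep(c(rep("single", 19), "jointB"), 60))
  expect_equal(stable_strategy(cp, 600)$group, "competitive")

  # step series: FST 0.8 for the first 300 events (s), then 1/3
  step_kinds <- c(rep(c(rep("single", 4), "jointA"), 60),
                  rep(c("single", "jointA", "jointB"), 500))
  st <- stable_strategy(mk(step_kinds), analysis_start = 600)
  expect_equal(st$group, "intermediate")
  expect_equal(st$phi, 1 / 3, tolerance = 0.01)
  expect_gt(st$convergence_s, 280)
  expect_lt(st$convergence_s, 430)

  # a session shorter than the analysis window errors
  expect_error(stable_strategy(mk(rep("single", 30)), 600), "shorter")
})

test_that("windowed FST counts reconstruct integer single-target tallies", {
  cy <- mixed_cycles()
  tc <- fst_timecourse(cy, window = 60)
  expect_true(all(tc$n_events >= 1))
  singles <- tc$fst * tc$n_events
  expect_true(all(abs(singles - round(singles)) < 1e-9))
  # a window covering the whole session recovers the session FST
  tc_all <- fst_timecourse(cy, window = max(cy$t_end_s) + 1)
  expect_equal(tc_all$fst[nrow(tc_all)], mean(cy$target_kind == "single"))
})

test_that("a block-inconsistent session raises the flag", {
  kinds <- c(rep("single", 600), rep("jointA", 600))
  cy <- data.frame(t_end_s = seq_along(kinds), target_kind = kinds,
                   payoff_a_cents = 3.5, payoff_b_cents = 3.5)
  s <- stable_strategy(cy, analysis_start = 100, block_duration = 600)
  expect_true(s$block_inconsistent)
})
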