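# Weighted choice rule and the free-agent placement optimizer.

test_that("the weighted rule reproduces the worked distance examples", {
  # both agents at the origin; relevant distances 10, 14, 20 cm
  targets <- rbind(single = c(10, 0), jointA = c(14, 0), jointB = c(20, 0))
  p <- c(0, 0)
  expect_equal(choose_target_weighted(targets, p, p, w = 0.5, lapse_p = 0), 1L)
  # w = 0.2: weighted (8, 2.8, 4) -> jointA
  expect_equal(choose_target_weighted(targets, p, p, w = 0.2, lapse_p = 0), 2L)
  # w = 1: the single target's weighted distance is zero
  for (seed in 1:20) {
    st <- init_session(cfg_std(), seed)
    expect_equal(choose_target_weighted(st$targets, st$pos[1, ], st$pos[2, ],
                                        w = 1, lapse_p = 0), 1L)
  }
})

test_that("full lapse gives a uniform choice over the three targets", {
  targets <- rbind(c(10, 0), c(14, 0), c(20, 0))
  p <- c(0, 0)
  draws <- withr::with_seed(99, replicate(3000, choose_target_weighted(
    targets, p, p, w = 0.9, lapse_p = 1)))
  expect_gt(stats::chisq.test(table(factor(draws, levels = 1:3)))$p.value, 0.01)
})

test_that("competitive placement sits next to the collector on the centre side", {
  cfg <- cfg_std()
  cache <- placement_cache(cfg, n_samples = 2000, seed = 1)
  centre <- rep(cfg$field_side / 2, 2)
  for (collector in list(c(35, 30), c(12, 40), c(40, 10))) {
    joints <- rbind(c(10, 10), c(45, 45))
    p <- advantageous_placement(collector, joints, "competitive", cache)
    expect_lt(sqrt(sum((p - collector)^2)), 5)
    expect_lt(sqrt(sum((p - centre)^2)), sqrt(sum((collector - centre)^2)))
  }
})

test_that("advantageous placement honours the joint-target proximity constraint", {
  cfg <- cfg_std()
  cache <- placement_cache(cfg, n_samples = 2000, seed = 1)
  withr::with_seed(3, {
    for (k in 1:10) {
      collector <- runif(2, 5, 46)
      joints <- matrix(runif(4, 5, 46), 2, 2)
      p <- advantageous_placement(collector, joints, "advantageous", cache)
      dj <- c(sqrt(sum((collector - joints[1, ])^2)),
              sqrt(sum((collector - joints[2, ])^2)))
      jstar <- joints[which.min(dj), ]
      expect_lte(sqrt(sum((p - jstar)^2)), min(dj) + cache$grid_step)
    }
  })
})

test_that("doubling the Monte-Carlo sample moves the placement objective by under 2%", {
  cfg <- cfg_std()
  c1 <- placement_cache(cfg, n_samples = 2000, seed = 1)
  c2 <- placement_cache(cfg, n_samples = 4000, seed = 2)
  collector <- c(35, 30)
  joints <- rbind(c(15, 15), c(40, 42))
  p1 <- advantageous_placement(collector, joints, "advantageous", c1)
  p2 <- advantageous_placement(collector, joints, "advantageous", c2)
  o1 <- attr(p1, "objective"); o2 <- attr(p2, "objective")
  expect_lt(abs(o1 - o2) / o2, 0.02)
})

test_that("policy parameters are validated", {
  expect_error(policy_params(w = 1.2))
  expect_error(policy_params(speed_factor = 0))
  expect_error(policy_params(lapse_p = -0.1))
  expect_error(policy_params(race_skill = 1.5))
  expect_s3_class(policy_params(), "ccf_policy")
})
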