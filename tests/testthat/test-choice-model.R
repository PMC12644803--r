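# Relevant distances, weighted prediction, weight fitting, the softmax
# choice model, entropy, and multi-dyad inference.

test_that("relevant distances take the min for singles and max for joints", {
  cy <- data.frame(ax_cm = 0, ay_cm = 0, bx_cm = 10, by_cm = 0,
                   single_x_cm = 4, single_y_cm = 0,
                   jointA_x_cm = 6, jointA_y_cm = 0,
                   jointB_x_cm = 20, jointB_y_cm = 0)
  d <- relevant_distances(cy)
  expect_equal(d$d_single, 4)   # min(4, 6)
  expect_equal(d$d_jointA, 6)   # max(6, 4)
  expect_equal(d$d_jointB, 20)  # max(20, 10)
})

test_that("relevant distances are invariant under the agent/joint mirror", {
  cy <- invite_cycles()
  d <- relevant_distances(cy)
  dm <- relevant_distances(mirror_cycles(cy))
  expect_equal(dm$d_single, d$d_single)
  expect_equal(dm$d_jointA, d$d_jointB)
  expect_equal(dm$d_jointB, d$d_jointA)
})

test_that("weighted prediction follows the arithmetic and reduces to closest at w = 0.5", {
  d <- data.frame(d_single = 10, d_jointA = 14, d_jointB = 20)
  expect_equal(predict_weighted(d, 0.5), "single")
  expect_equal(predict_weighted(d, 0.2), "jointA")
  cy <- mixed_cycles()
  dd <- relevant_distances(cy)
  closest <- c("single", "jointA", "jointB")[apply(as.matrix(dd), 1, which.min)]
  expect_equal(predict_weighted(dd, 0.5), closest)
})

test_that("the fitted weight reproduces the generating FST", {
  sw <- strategy_sweep(cfg_std(), w_grid = 0.5, n_cycles = 2000, seed = 8,
                       keep_cycles = TRUE)
  cy <- attr(sw, "cycles")[[1]]
  w <- fit_weight(cy)
  expect_equal(attr(w, "predicted_fst"), attr(w, "observed_fst"),
               tolerance = 0.02)
  # on these lapse-free cycles the generating weight itself is recovered
  expect_equal(as.numeric(w), 0.5, tolerance = 0.05)
})

test_that("the weight fit hits the boundaries and is monotone", {
  cy <- mixed_cycles()
  all_single <- cy; all_single$target_kind <- "single"
  expect_equal(as.numeric(fit_weight(all_single)), 1)
  all_joint <- cy; all_joint$target_kind <- "jointA"
  expect_equal(as.numeric(fit_weight(all_joint)), 0)
  d <- relevant_distances(cy)
  fst_w <- sapply(seq(0, 1, 0.1), function(w)
    mean(predict_weighted(d, w) == "single"))
  expect_true(all(diff(fst_w) >= 0))
  expect_error(fit_weight(cy[1:10, ]), "20 cycles")
})

test_that("the design flags invitations and mirrors consistently", {
  cy <- invite_cycles()
  des <- build_design(cy)
  expect_gt(sum(des$invite != "none"), 10)
  # hand-check one invitation row: one agent within the radius of that
  # joint at cycle start, the other not on it
  i <- which(des$invite == "jointA")[1]
  row <- cy[des$kept[i], ]
  da <- sqrt((row$ax_cm - row$jointA_x_cm)^2 + (row$ay_cm - row$jointA_y_cm)^2)
  db <- sqrt((row$bx_cm - row$jointA_x_cm)^2 + (row$by_cm - row$jointA_y_cm)^2)
  expect_true(xor(da <= des$invite_radius, db <= des$invite_radius))

  # mirroring the log mirrors the design feature-wise
  desm <- build_design(mirror_cycles(cy))
  expect_equal(desm$za, des$zb)
  expect_equal(desm$zb, des$za)
  swap <- c(single = "single", jointA = "jointB", jointB = "jointA")
  expect_equal(unname(swap[des$y]), desm$y)
})

test_that("no agent near a joint target means no invitation flag", {
  cy <- invite_cycles()[3:50, ]
  cy$ax_cm <- 0; cy$ay_cm <- 0; cy$bx_cm <- 51; cy$by_cm <- 0
  cy$jointA_x_cm <- 25; cy$jointA_y_cm <- 25
  cy$jointB_x_cm <- 10; cy$jointB_y_cm <- 40
  des <- build_design(cy)
  expect_true(all(des$invite == "none"))
})

test_that("softmax probabilities are normalized and shift-invariant", {
  des <- invite_design()
  fit <- invite_fit()
  expect_true(all(abs(rowSums(fit$prob) - 1) < 1e-9))
  # adding a constant to every class score leaves probabilities unchanged:
  # the score of the reference class is fixed at zero, so shift the other
  # two via an intercept change and verify the invariance analytically
  p1 <- ccforage:::softmax_probs(fit$theta, des$za, des$zb)
  u <- cbind(0, des$za %*% fit$theta, des$zb %*% fit$theta) + 5
  p2 <- exp(u - apply(u, 1, max))
  p2 <- p2 / rowSums(p2)
  expect_equal(unname(p1), unname(p2), tolerance = 1e-12)
})

test_that("model accuracy is nested: closest <= weighted <= full (within tolerance)", {
  cy <- invite_cycles()
  acc_closest <- cv_accuracy_rule(cy, "closest")
  acc_weighted <- cv_accuracy_rule(cy, "weighted")
  fit <- invite_fit()
  expect_gte(acc_weighted, acc_closest - 0.02)
  expect_gte(fit$cv_accuracy, acc_weighted - 0.02)
  # history/invitation structure in this policy gives the full model a
  # clear edge over distance-only prediction
  expect_gt(fit$cv_accuracy, acc_weighted + 0.05)
  # and AIC improves on the distance-only softmax
  dfit <- suppressWarnings(fit_glm(invite_design(), model = "distance"))
  expect_lt(fit$aic, dfit$aic)
})

test_that("an injected invitation effect is recovered with a significant positive sign", {
  fit <- invite_fit()
  expect_gt(fit$theta[["invite_own"]], 0)
  expect_lt(fit$wald_p[["invite_own"]], 0.05)
})

test_that("prediction entropy matches its closed forms and bounds", {
  expect_equal(prediction_entropy(c(1, 0, 0)), 0)
  expect_equal(prediction_entropy(c(0.5, 0.5, 0)), 1)
  expect_equal(prediction_entropy(rep(1 / 3, 3)), log2(3))
  expect_error(prediction_entropy(c(0.5, 0.2, 0.2)), "sum to 1")
  h <- invite_fit()$entropy_bits
  expect_true(all(h >= 0 & h <= log2(3) + 1e-12))
})

test_that("lapses raise the model's prediction entropy", {
  cfg <- cfg_std()
  mk <- function(lapse) {
    p <- policy_params(w = 0.5, lapse_p = lapse, reaction_jitter = 0.2)
    ses <- simulate_dyad(cfg, p, p, 500, seed = 15)
    suppressWarnings(fit_glm(build_design(segment_cycles(ses))))
  }
  expect_gt(mean(mk(0.5)$entropy_bits), mean(mk(0)$entropy_bits))
})

test_that("Benjamini-Hochberg and the sign-consistency binomial follow the textbook rules", {
  mkfit <- function(p, theta) structure(list(
    theta = stats::setNames(rep(theta, 3), c("a", "b", "c")),
    wald_p = stats::setNames(rep(p, 3), c("a", "b", "c"))),
    class = "ccf_choice_fit")
  # single test: BH leaves the p-value alone
  res1 <- coefficient_tests(list(mkfit(0.03, 1)))
  expect_equal(unname(attr(res1, "bh_p")[1, 1]), 0.03)
  # hand-applied step-up rule on (0.01, 0.02, 0.9)
  fits <- list(mkfit(0.01, 1), mkfit(0.02, 1), mkfit(0.9, 1))
  expect_equal(unname(attr(coefficient_tests(fits), "bh_p")[, 1]),
               c(0.03, 0.03, 0.9))
  # 29 of 30 significant coefficients positive: exact binomial p < 1e-6
  expect_lt(stats::binom.test(29, 30, 0.5)$p.value, 1e-6)
})

test_that("the uniform baseline scores exactly one third", {
  expect_identical(uniform_baseline_accuracy(invite_cycles()$target_kind), 1 / 3)
})

test_that("the full model matches the FST fluctuation size better than the weighted rule", {
  # the weighted rule over-fluctuates (random layouts drive it); the full
  # model, which knows about invitations and history, reproduces the size
  # of the actual 30-s moving-average FST fluctuations more closely
  cy <- invite_cycles()
  des <- invite_design()
  fit <- invite_fit()
  kept <- cy[des$kept, ]
  sd_act <- stats::sd(fst_timecourse(kept, window = 30)$fst)
  sd_full <- stats::sd(predicted_fst_series(kept, fit$predicted, window = 30)$fst)
  w <- fit_weight(cy)
  sd_wt <- stats::sd(predicted_fst_series(
    kept, predict_weighted(relevant_distances(kept), as.numeric(w)),
    window = 30)$fst)
  expect_lt(abs(sd_full - sd_act), abs(sd_wt - sd_act))
})
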