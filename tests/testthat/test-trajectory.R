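# Heuristic trajectory classes, Markov transitions, entropy linkage.

test_that("classification is exhaustive and mutually exclusive", {
  labs <- invite_labels()
  known <- c("invitation", "failed_invitation", "strongly_curved",
             "different_targets", "one_ahead", "concurrent", "unclassifiable")
  expect_true(all(labs$label %in% known))
  expect_equal(nrow(labs), nrow(invite_cycles()))
  expect_true(all(labs$curvature_a >= 1, na.rm = TRUE))
})

test_that("a dwelling agent whose joint target is then collected is an invitation", {
  cy <- invite_cycles()
  labs <- invite_labels()
  expect_true(any(labs$label == "invitation" & labs$sublabel == "passive"))
  # invitation cycles end in a joint collection
  inv <- labs$label == "invitation"
  expect_true(all(cy$target_kind[inv] != "single"))
  # failed invitations end elsewhere (the partner rejected and raced off)
  fl <- labs$label == "failed_invitation"
  expect_true(any(fl))
  expect_true(all(cy$target_kind[fl] == "single"))
})

test_that("noiseless simultaneous dyads are almost entirely concurrent", {
  cy <- segment_cycles(clean_session())
  labs <- classify_session(cy)
  ok <- !labs$label %in% c("invitation", "failed_invitation", "unclassifiable")
  expect_gte(mean(labs$label[ok] == "concurrent"), 0.99)
})

test_that("miscoordinated joint choices produce strongly curved yield paths", {
  p <- policy_params(w = 0.15, lapse_p = 0.3, miscoord_p = 1,
                     reaction_jitter = 0, hover_drift = 0)
  ses <- simulate_dyad(cfg_std(), p, p, 250, seed = 33)
  labs <- classify_session(segment_cycles(ses))
  curved <- labs$label == "strongly_curved"
  expect_gt(sum(curved), 5)
  expect_true(all(pmax(labs$curvature_a, labs$curvature_b)[curved] > 1.25))
})

test_that("a scripted lead produces the one-ahead class", {
  pa <- policy_params(w = 0.5, reaction_delay = 0)
  pb <- policy_params(w = 0.5, reaction_delay = 0.5)
  ses <- simulate_dyad(cfg_std(), pa, pb, 150, seed = 12)
  labs <- classify_session(segment_cycles(ses))
  expect_gt(mean(labs$label == "one_ahead"), 0.5)
})

test_that("transition counts follow the hand example and rows are stochastic", {
  tr <- transition_chain(c("concurrent", "concurrent", "invitation"))
  expect_equal(tr$counts["concurrent", "concurrent"], 1L)
  expect_equal(tr$counts["concurrent", "invitation"], 1L)
  rs <- rowSums(tr$prob)
  expect_true(all(abs(rs[!tr$undefined_rows] - 1) < 1e-12))
  expect_true(all(is.na(tr$prob[tr$undefined_rows, ])))
  expect_error(transition_chain("concurrent"), "at least 2")

  trf <- transition_chain(invite_labels()$label)
  rs <- rowSums(trf$prob)
  expect_true(all(abs(rs[!trf$undefined_rows] - 1) < 1e-12))
})

test_that("a failed invitation is most often followed by an accepted one", {
  tr <- transition_chain(invite_labels()$label)
  row <- tr$prob["failed_invitation", ]
  expect_false(tr$undefined_rows["failed_invitation"])
  expect_equal(names(which.max(row)), "invitation")
})

test_that("labels are invariant under the agent/joint mirror", {
  cy <- invite_cycles()
  labs <- invite_labels()
  labsm <- classify_session(mirror_cycles(cy))
  expect_equal(labsm$label, labs$label)
})

test_that("class fractions partition each entropy bin", {
  labs <- invite_labels()
  des <- invite_design()
  h <- invite_fit()$entropy_bits
  tab <- entropy_by_class(labs$label[des$kept], h)
  sums <- tapply(tab$fraction, tab$bin, sum)
  occupied <- !is.na(sums)
  expect_true(all(abs(sums[occupied] - 1) < 1e-9))
  # degenerate case: a single class occupies every bin fully
  tab1 <- entropy_by_class(rep("concurrent", 50), seq(0.1, 1.5, length.out = 50))
  occ <- !is.na(tab1$fraction)
  expect_true(all(tab1$fraction[occ & tab1$label == "concurrent"] == 1))
  expect_true(all(tab1$fraction[occ & tab1$label != "concurrent"] == 0))
})

test_that("invitations reduce the model's choice uncertainty", {
  labs <- invite_labels()
  des <- invite_design()
  fit <- invite_fit()
  h <- fit$entropy_bits
  inv <- labs$label[des$kept] == "invitation"
  expect_lt(mean(h[inv]), mean(h[!inv]))
  res <- invitation_entropy_test(fit, des)
  expect_lt(res$p_value, 0.05)
  expect_lt(res$median_with, res$median_without)
  expect_lt(res$rank_biserial, 0)
})
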