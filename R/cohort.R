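# Cohort-level plumbing: run the full per-session analysis chain and
# assemble per-dyad records across a simulated cohort spanning the
# cooperation-competition spectrum.

#' Analyze one session end to end
#'
#' Convenience wrapper running cycle segmentation, trajectory
#' classification, per-cycle kinematics, the payoff approximation and the
#' skill estimate on one session.
#'
#' @param session A `ccf_session`.
#' @param classify_params Thresholds for [classify_session()].
#' @return List with `cycles`, `labels`, `kinematics`, `decomposition`,
#'   `payoff`, `skill`, and `phi` (session-level FST).
#' @export
analyze_session <- function(session, classify_params = NULL) {
  cycles <- segment_cycles(session)
  if (is.null(classify_params)) classify_params <- classify_params()
  labels <- classify_session(cycles, classify_params)
  kin <- cycle_kinematics(cycles)
  list(
    cycles = cycles,
    labels = labels,
    kinematics = kin,
    decomposition = length_decomposition(kin),
    payoff = suppressWarnings(payoff_approximation(kin, cycles)),
    skill = estimate_skill(cycles, labels),
    phi = mean(cycles$target_kind == "single")
  )
}

#' One-row per-dyad record
#'
#' @param session A `ccf_session`.
#' @param dyad_id Identifier stored in the record.
#' @return One-row data frame with the dyad's FST, payoffs, payoff rates
#'   (actual and length/speed estimate), length-decomposition components,
#'   limiting speed, and skill estimate -- the input format of
#'   [fit_counterfactual_model()].
#' @export
dyad_record <- function(session, dyad_id = 1L) {
  a <- analyze_session(session)
  cy <- a$cycles
  total_t <- cy$t_end_s[nrow(cy)] - cy$t_start_s[1L]
  data.frame(
    dyad_id = dyad_id,
    phi = a$phi,
    n_cycles = nrow(cy),
    duration_s = total_t,
    payoff_a_cents = sum(cy$payoff_a_cents),
    payoff_b_cents = sum(cy$payoff_b_cents),
    payoff_rate_actual = a$payoff$actual_rate,
    payoff_rate_estimated = a$payoff$estimated_rate,
    mean_limiting_cm = a$decomposition$mean_limiting_cm,
    straight_cm = a$decomposition$straight_cm,
    placement_cm = a$decomposition$placement_cm,
    curvature_cm = a$decomposition$curvature_cm,
    speed_cm_s = a$decomposition$mean_speed_cm_s,
    skill_diff = a$skill$skill_diff,
    skill_defined = a$skill$defined,
    contested = a$skill$contested,
    stringsAsFactors = FALSE
  )
}

#' Simulate a cohort of dyads spanning the strategy spectrum
#'
#' Simulates `n_dyads` sessions whose preference weights cover `[0, 1]`, so
#' realized FST values span the cooperation-competition spectrum. Base
#' movement speed rises mildly with the preference weight (mirroring the
#' empirical tendency of competitive dyads to move faster), and a cyclic
#' pattern of within-dyad speed asymmetries plants competitive skill
#' differences.
#'
#' @param config A [game_config()].
#' @param n_dyads Number of dyads.
#' @param n_cycles Collection cycles per dyad.
#' @param seed Integer seed.
#' @param w_values Preference weights (recycled/defaulted to an even grid).
#' @param speed_base Cycle of base speed factors across dyads (spanning the
#'   speed diversity of a cohort).
#' @param speed_slope Increase of the speed factor from `w = 0` to `w = 1`.
#' @param asymmetries Cycle of within-dyad competitive skill differences
#'   (see `race_skill` in [policy_params()]); positive values favour agent
#'   A in contested races.
#' @param reaction_delay,reaction_jitter Mean and uniform per-cycle spread
#'   of the reaction delay (s), shared by all agents.
#' @param miscoord_p Dyad-level miscoordination probability.
#' @return Data frame of [dyad_record()] rows (one per dyad), with the
#'   planted `w`, speed factors and asymmetry as extra columns.
#' @export
simulate_cohort <- function(config, n_dyads = 30, n_cycles = 500, seed = 1,
                            w_values = NULL,
                            speed_base = 0.72,
                            speed_slope = 0.25,
                            asymmetries = c(0, 0.15, 0.3),
                            reaction_delay = 0.15, reaction_jitter = 0.35,
                            miscoord_p = 0.05) {
  if (is.null(w_values))
    w_values <- seq(0, 1, length.out = n_dyads)
  w_values <- rep_len(w_values, n_dyads)
  base <- rep_len(speed_base, n_dyads)
  asym <- rep_len(asymmetries, n_dyads)
  # Speed scales with the dyad's FST (as observed empirically: competitive
  # dyads move faster). The expected FST of each weight is taken from a
  # cheap event-level sweep so that speed is a function of the strategy
  # actually realized, not of the raw weight.
  fst_of_w <- strategy_sweep(config, w_grid = sort(unique(w_values)),
                             placement = "none", n_cycles = 500,
                             seed = child_seed(seed, 17L))
  fst_proxy <- fst_of_w$fst[match(w_values, fst_of_w$w)]
  recs <- vector("list", n_dyads)
  for (i in seq_len(n_dyads)) {
    sa <- sb <- min(1, base[i] + speed_slope * fst_proxy[i])
    pa <- policy_params(w = w_values[i], speed_factor = sa,
                        reaction_delay = reaction_delay,
                        reaction_jitter = reaction_jitter,
                        race_skill = 0.5 + asym[i] / 2,
                        miscoord_p = miscoord_p)
    pb <- policy_params(w = w_values[i], speed_factor = sb,
                        reaction_delay = reaction_delay,
                        reaction_jitter = reaction_jitter,
                        race_skill = 0.5 - asym[i] / 2,
                        miscoord_p = miscoord_p)
    ses <- simulate_dyad(config, pa, pb, n_cycles,
                         seed = child_seed(seed, 1000L + i))
    rec <- dyad_record(ses, dyad_id = i)
    rec$w <- w_values[i]
    rec$speed_factor_a <- sa
    rec$speed_factor_b <- sb
    rec$planted_asymmetry <- asym[i]
    recs[[i]] <- rec
  }
  do.call(rbind, recs)
}
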