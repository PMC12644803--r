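# Competitive skill difference and the cost of cooperation: contested
# single-target races estimate the within-dyad skill asymmetry; component
# fits across dyads give a counterfactual payoff-vs-FST model from which
# the payoff forgone by cooperating (relative to fully competitive play)
# is derived for the higher-skilled agent.

#' Estimate the competitive skill difference
#'
#' Contested cycles are those classified "one ahead" or "concurrent" to the
#' same target with a single-target outcome and both agents actually racing
#' (solo-pursuit cycles are excluded). The skill difference is the
#' normalized win difference `(wins_A - wins_B) / contested`, in `[-1, 1]`;
#' it is undefined for dyads that never contest a single target (fully
#' cooperative play).
#'
#' @param cycles A `ccf_cycles` frame.
#' @param labels Classification from [classify_session()].
#' @return List with `contested`, `wins` (named A/B), `skill_diff`,
#'   `defined`.
#' @export
estimate_skill <- function(cycles, labels) {
  stopifnot(nrow(cycles) == nrow(labels))
  contested <- labels$label %in% c("one_ahead", "concurrent") &
    labels$sublabel == "single" & cycles$target_kind == "single"
  n <- sum(contested)
  if (n == 0L)
    return(list(contested = 0L, wins = c(A = 0L, B = 0L),
                skill_diff = NA_real_, defined = FALSE))
  wa <- sum(cycles$collector[contested] == "A")
  wb <- n - wa
  list(contested = n, wins = c(A = wa, B = wb),
       skill_diff = (wa - wb) / n, defined = TRUE)
}

#' Fit the counterfactual payoff model across dyads
#'
#' Fits the payoff-shaping components -- counterfactual straight distance,
#' placement reduction, curvature excess and limiting speed -- as quadratic
#' functions of the stable FST `phi` across dyads. The expected joint
#' payoff per session is then
#' `R(phi) = session_duration * payoff_single / (length(phi)/speed(phi) + hover_time)`
#' with `length = straight - placement + curvature`, and the expected
#' individual payoff of an agent with competitive skill difference `s` is
#' `R_x(phi) = R(phi) * (1 + s * phi) / 2`: the joint payoff splits evenly
#' except for the contested single-target share, which tilts by the win
#' asymmetry. At `phi = 0` skill cannot create a payoff difference; at
#' equal skill each agent earns half the joint payoff at every FST.
#'
#' @param records Data frame with one row per dyad: `phi`, `straight_cm`,
#'   `placement_cm`, `curvature_cm`, `speed_cm_s` (typically assembled from
#'   [length_decomposition()] via [dyad_record()]).
#' @param config A [game_config()] (session duration, payoff, hover time).
#' @return Object of class `ccf_payoff_model` with the component fits and a
#'   `predict`-style interface ([predict_joint_payoff()],
#'   [predict_individual_payoff()]).
#' @export
fit_counterfactual_model <- function(records, config) {
  stopifnot(all(c("phi", "straight_cm", "placement_cm", "curvature_cm",
                  "speed_cm_s") %in% names(records)))
  if (nrow(records) < 10L)
    warning("fewer than 10 dyads; component fits will be unstable")
  if (diff(range(records$phi)) < 0.5)
    warning("phi coverage is narrow (< 0.5); counterfactual extrapolation flagged")
  qfit <- function(y) stats::lm(y ~ phi + I(phi^2), data = records)
  fits <- list(
    straight = qfit(records$straight_cm),
    placement = qfit(records$placement_cm),
    curvature = qfit(records$curvature_cm),
    speed = qfit(records$speed_cm_s)
  )
  structure(list(fits = fits, config = config,
                 phi_range = range(records$phi), n_dyads = nrow(records)),
            class = "ccf_payoff_model")
}

component_at <- function(model, phi) {
  nd <- data.frame(phi = phi)
  p <- lapply(model$fits, stats::predict, newdata = nd)
  len <- pmax(p$straight - p$placement + p$curvature, 1)
  spd <- pmax(p$speed, 1)
  list(length_cm = len, speed_cm_s = spd)
}

#' Expected joint payoff at a given FST
#'
#' @param model A `ccf_payoff_model`.
#' @param phi FST value(s) in `[0, 1]`.
#' @return Expected joint payoff per session block (cents).
#' @export
predict_joint_payoff <- function(model, phi) {
  cfg <- model$config
  cmp <- component_at(model, phi)
  dur <- cmp$length_cm / cmp$speed_cm_s + cfg$hover_time
  cfg$session_duration * cfg$payoff_single / dur
}

#' Expected individual payoff at a given FST and skill difference
#'
#' @param model A `ccf_payoff_model`.
#' @param phi FST value(s).
#' @param skill_diff Signed competitive skill difference of the agent
#'   (positive: this agent wins more contested singles).
#' @return Expected individual payoff per session block (cents).
#' @export
predict_individual_payoff <- function(model, phi, skill_diff) {
  r <- predict_joint_payoff(model, phi)
  r * (1 + skill_diff * phi) / 2
}

#' Cost of cooperation for the higher-skilled agent
#'
#' The payoff the higher-skilled agent forgoes by playing at the observed
#' FST instead of the fully competitive `phi = 1` counterfactual, assuming
#' the skill difference is independent of FST. Zero when the dyad already
#' plays at `phi = 1`; only meaningful for the positive-skill side.
#'
#' @param model A `ccf_payoff_model`.
#' @param phi_obs The dyad's observed stable FST.
#' @param skill_diff The dyad's signed skill difference (see
#'   [estimate_skill()]); its absolute value is used.
#' @return Cost in cents, with attributes `extrapolated` (whether `phi = 1`
#'   lies outside the fitted range) and `included` (`phi_obs < 0.9`, the
#'   cohort the analysis reports on).
#' @export
cost_of_cooperation <- function(model, phi_obs, skill_diff) {
  if (is.na(skill_diff))
    stop("skill difference undefined; no cost estimate", call. = FALSE)
  s <- abs(skill_diff)
  cost <- predict_individual_payoff(model, 1, s) -
    predict_individual_payoff(model, phi_obs, s)
  structure(cost,
            extrapolated = model$phi_range[2L] < 0.95,
            included = phi_obs < 0.9)
}
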