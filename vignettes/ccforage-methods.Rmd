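---
title: "Models and methods behind ccforage"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind ccforage}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models implemented in `ccforage`, the choices
made where a published description leaves details open, and what the
synthetic-data generator does and does not emulate. It states no numbers
that the test suite and the analysis scripts do not themselves compute.

## The game

Two agents forage on a square field (side 51 cm) holding one single target
and two joint targets (5 cm diameter) at all times. An agent collects a
target by keeping its centre inside the target circle for one second
(120 ticks at 120 Hz); a joint target requires both agents inside
simultaneously, and leaving before completion resets that target's
progress. The single target pays 7 cents to the claimant — the first agent
to occupy it — while a joint target pays 5 cents to the favoured and 2 to
the other agent, so both target types carry the same 7-cent joint payoff
and neither is a priori more valuable to the dyad. Collected targets
respawn uniformly at random (rejection-sampled so that no two targets
overlap and every target lies fully inside the field); agents and the two
remaining targets stay put, so collection cycles chain continuously.
Commanded velocities above 42.6 cm/s are clipped with direction preserved.

Choices the rules do not pin down, made here once:

* **Occupancy** is agent *centre* inside the target circle (radius
  2.5 cm) — the simplest rotation-invariant rule.
* **Simultaneous same-tick arrival** at the single target is broken by a
  seeded coin flip.
* **Coordinates**: origin at the lower-left field corner, x rightward,
  y upward, centimetres.
* **Hover accounting**: the entry tick establishes occupancy and progress
  accrues on subsequent ticks, so collection completes exactly one second
  after entry.

`step_game()` is the per-tick contract; `simulate_dyad()` advances
event-by-event along piecewise-linear legs and materializes the 120 Hz
trajectories by interpolation. The test suite replays a simulated
velocity stream through the per-tick engine and checks that both paths
agree event for event — the fast path is an optimization, not a second
rule set.

## Synthetic dyads: what the generator emulates

`policy_params()` spans the strategy spectrum observed in human dyads:

* `w` — the preference weight of the choice rule
  `argmin{D_S(1−w), D_JA·w, D_JB·w}` over the relevant distances
  (minimum over agents for the single target, maximum for joint targets).
  One shared draw per cycle models dyadic coordination;
  `miscoord_p` (default 0.05 in the cohort) lets the agents draw
  independently, producing "different targets" cycles and, when both head
  to different joint targets, a deadlock resolved by a seeded yielder
  whose detour produces strongly curved paths.
* `lapse_p` — probability of ignoring the rule and choosing uniformly
  (the 70%/90% rule-following variants of the landscape analysis).
* `placement_mode` — what the free agent does during a single-target
  collection: `advantageous` (grid-optimized expected-distance
  placement), `competitive` (maximize the probability of being closer
  than the collector to the next single target), `invite` (park on the
  nearer joint target and stay), `split_field` (each agent owns its
  half-field), or `none`.
* `speed_factor`, `reaction_delay`, `reaction_jitter` — kinematics:
  straight pursuit at `speed_factor × 42.6` cm/s after a per-cycle delay
  `reaction_delay + U(0, reaction_jitter)`. Cohort defaults (0.15 s delay,
  0.35 s jitter) are ordinary human reaction-time scales.
* `race_skill` — competitive skill as a direct win-probability dial: when
  both agents race for the single target, agent A wins with probability
  `0.5 + (race_skill_A − race_skill_B)/2`. The designated winner sheds
  reaction delay as needed so the claim still happens at the kinematically
  earliest arrival, and the designated loser pulls up at the target rim;
  trajectories stay physical and the planted skill difference is expressed
  identically at every FST. We added this dial after finding that purely
  kinematic skill knobs (delay or speed offsets) express *more* strongly in
  the near-co-located races that follow joint collections than in spread
  races — i.e. their effective skill difference depends on FST, which is
  exactly the independence assumption the counterfactual payoff model
  needs. With equal `race_skill` the race is decided by kinematics alone.
* `hover_drift` (default 3 cm) — small random repositioning during the
  1-s hover: collectors drift to a random point inside the target (paths
  between two points of a disk stay inside it, so occupancy is never
  broken), free agents drift freely but never park on a target. Without
  it, both agents restart *exactly* co-located after every joint
  collection — an artifact a cursor-controlled human never produces — and
  contested races following joints degenerate into pure reaction-time
  races.
* `invite_accept` — probability of accepting a standing invitation (an
  agent resting on a joint target at cycle start). Rejection sends the
  partner to the single target, so failed invitations are typically
  followed by a retried, accepted one.
* `turn_taking` — strict alternation between the two joint targets
  regardless of distance (the fully cooperative normative strategy).

The generator does **not** model: adaptive or learning policies, curved
human motor trajectories beyond miscoordination detours, online mutual
prediction during movement, or visual access effects. Passing tests
therefore demonstrate correctness of the analysis chain on controllable
ground truth, not validity of any claim about human data.

### The study cohort

`simulate_cohort()` (30 dyads, 500 cycles each by default) spreads `w`
evenly over [0, 1], plants skill differences cycling {0, 0.15, 0.3}, and
ties the speed factor to the dyad's *expected* FST
(`0.72 + 0.25 × FST`, i.e. roughly 31–41 cm/s), mirroring the empirical
tendency of competitive dyads to move faster. Speed is tied to expected
FST — estimated from a cheap event-level sweep — rather than to the raw
weight, because the weight→FST map saturates near the extremes and speed
would otherwise vary invisibly to any FST-indexed model. Session length
of 500 cycles is of the order of (somewhat below) a real 40-minute
session.

## The strategy landscape

`strategy_sweep()` is an event-level idealized simulation (straight lines
at the speed cap, no reaction delay, co-located restarts unless placement
is active): exactly the regime in which path-minimization theory makes
its predictions. The advantageous-placement objective
`E_s[min(d(p, s), d(collector, s))]` is evaluated on a 1-cm candidate
grid against a fixed seeded Monte-Carlo sample of 2,000 future
single-target positions, subject to the constraint that the free agent
ends no farther from the joint target nearest the collector than the
collector itself. Landscapes are cached per collector cell snapped to a
3-cm grid — the objective varies smoothly with collector position, and
caching is what keeps a full weight sweep in the minutes range. The
competitive variant maximizes `Pr_s[d(p, s) < d(collector, s)]`,
unconstrained; its optimum sits just beside the collector on the
field-centre side.

Because the payoff-rate curve is nearly flat around its maximum,
`optimal_fst()` smooths payoff against FST (loess, local quadratic,
span 0.75) before locating the maximum; the raw per-grid-point argmax is
available but fluctuates strongly between seeds on a flat plateau.

## The choice model

Features per cycle: the three relevant distances, standardized within the
dyad (the two joint distances share pooled mean and SD so standardization
preserves the relabelling symmetry), indicators for the kinds collected
in the two previous cycles (cycles 1–2 are dropped from model fits), and
the invitation indicator with the invited joint's identity
(`invite_radius` defaults to the 2.5 cm target radius; how near is "near
a joint target" is a convention of this implementation, exposed as an
argument).

The A/B interchangeability of the game is built in by parameter tying:
with the single-target score as the softmax gauge zero, the jointA and
jointB scores share one 10-parameter coefficient vector applied in "own"
and mirrored coordinates. This is likelihood-identical to augmenting the
data with mirrored rows sharing θ, but gives an unambiguous free-parameter
count for AIC (k = 10; 4 for the distance-only variant) and per-coefficient
Wald tests with direct interpretations (`invite_own` is *the* invitation
effect). `mirror_cycles()` exposes the mirror operation so
swap-equivariance is testable.

Numerics: BFGS from a zero start (`optim`, relative tolerance 1e-12), a
post-hoc gradient check at 1e-6, and — on non-convergence or runaway
coefficients, e.g. under complete separation — a refit with L2 ridge 1e-4
and a warning. Cross-validation uses contiguous blocks of cycles (5 by
default) to respect serial dependence; the closest and weighted rules are
evaluated with the same folds (the weight refitted per training fold) so
the three tiers are comparable. `fit_weight()` matches predicted to
observed FST by monotone bisection to within 1/n; an unreachable FST
returns the boundary weight. Degenerate inputs: all-joint dyads fit w = 0,
all-single w = 1; a perfectly separated invitation column yields an
honest near-singular Wald direction (flagged, not hidden).

Prediction entropy is `−Σ p log₂ p` with `0·log 0 = 0`, clamped to
[0, log₂ 3] against floating-point drift. The invitation-entropy analysis
pairs, per cycle, the fitted model's entropy with the entropy after
zeroing the invitation features, and tests invitation-bearing cycles by
Wilcoxon signed rank with a rank-biserial effect size.

## Trajectory classification

Rules are applied in order; the first match labels the cycle:
(1) *invitation* — an agent continuously within the capture radius of a
joint target for at least `t_dwell` before cycle start, and that target
collected (*passive* if the dwell spans the whole previous collection
period, *active* otherwise); (2) *failed invitation* — such a dwell, but
another target collected; (3) *strongly curved* — either agent's
path-length/chord ratio above `c_thr` during acquisition; (4) *different
targets* — the agents end the acquisition at different targets;
(5) *one ahead* — both to the collected target with movement-onset lag
above `t_lead`; (6) *concurrent* otherwise. Movement onset is the first
tick at which speed toward the collected target exceeds 10% of the speed
cap for three consecutive ticks. Trajectories shorter than three samples
are flagged unclassifiable.

The thresholds (`c_thr` = 1.25, `t_lead` = 0.25 s, `t_dwell` = 0.5 s,
capture radius = target radius, minimum chord 1 cm under which the
curvature ratio is taken as 1) are conventions of this implementation —
the classes and their order define the scheme, the cutoffs
operationalize it — and are all arguments of `classify_params()` for
sensitivity analysis. Cycles in
which only one agent ever onsets toward the target are sub-labelled
`_solo`, and skill estimation counts only genuinely contested races
(both onsets, single-target outcome, one-ahead or concurrent class).

## Payoff decomposition and the counterfactual model

The limiting agent is the collector (single targets) or the last-entering
agent (joint targets). Its path length over the acquisition, divided by
the full acquisition time, gives the mean speed — the reaction delay is
deliberately *not* subtracted: movement-phase averaging (onset-based
denominators) is available via an argument but is numerically fragile for
near-stationary limiting agents. Straight distances are measured to the
capture radius (path ends at target entry), which keeps
`curvature_excess ≥ 0` exact. The placement reduction compares against a
counterfactual start at the previous collection point, making the
decomposition `length = straight − placement + curvature` an exact
identity over cycles 2…n.

The counterfactual payoff model fits each component (counterfactual
straight distance, placement reduction, curvature excess, limiting speed)
as a quadratic in Φ across the cohort — a deliberately smooth, low-order
family for 30-ish dyads; the degree is not dogma and the fits are plain
`lm` objects. The joint payoff is
`R̂(Φ) = T · 7 / (length(Φ)/speed(Φ) + 1)` cents per block of T = 1200 s,
and the individual payoff `R̂ˣ(Φ) = R̂(Φ)(1 + s·Φ)/2`: the joint payoff
splits evenly except for the single-target share, which tilts with the
skill difference s. This construction ignores joint-target bias (which
asymmetric joint collections would add) — the within-dyad payoff
difference is dominated by single-target wins. The cost of cooperation is
`R̂ˣ(1) − R̂ˣ(Φ_obs)` for the higher-skilled side, assuming s independent
of Φ — an assumption the generator honours by construction of
`race_skill`, and which for human data is exactly that: an assumption.
Extrapolation beyond the fitted Φ range and narrow Φ coverage
(range < 0.5) are flagged.

## Problem sizes and tolerances used by the checks

The packaged checks run at desk scale, sized so the full suite completes
in minutes while keeping Monte-Carlo noise below the tolerances they
assert: weight sweeps at 2,000 cycles per grid point (4,000 in the
acceptance script), the cohort at 30 dyads × 500 cycles, model-fit
fixtures at 400–600 cycles, skill recovery at ~400 contested races per
dyad, and the cost-of-cooperation oracle comparing five 3,000-cycle
sessions against re-simulated 4,000-cycle fully competitive
counterfactuals at a planted skill difference of +0.2.

## Known limitations

* Human trajectories curve for reasons the generator does not model
  (online mutual prediction, motor noise, changes of mind); curvature in
  simulations arises only from miscoordination detours.
* The classifier thresholds and the invitation radius are conventions;
  conclusions that hinge on exact class frequencies should sweep them.
* The counterfactual model extrapolates component fits to Φ = 1 for
  cooperative cohorts; with few competitive dyads this is flagged but
  still an extrapolation.
* Skill estimates from few contested races are numerically defined but
  meaningless; the analysis scripts require ≥ 20 contested races before
  reporting a cost of cooperation.
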