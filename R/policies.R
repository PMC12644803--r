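# Agent policies: the weighted distance-based target choice rule, the
# placement optimizer used by the free agent during single-target
# collections, and the parameter container spanning the
# cooperation-competition spectrum.

#' Relevant distances of a target layout
#'
#' For the single target the relevant distance is the minimum over the two
#' agents (either agent can collect it); for a joint target it is the maximum
#' (the last-arriving agent limits the collection).
#'
#' @param pos_a,pos_b Agent positions (length-2 numerics, cm).
#' @param targets 3 x 2 matrix of target centres in the kind order single,
#'   jointA, jointB.
#' @return Named numeric vector `c(single=, jointA=, jointB=)` (cm).
#' @export
layout_distances <- function(pos_a, pos_b, targets) {
  da <- dist_to(pos_a, targets)
  db <- dist_to(pos_b, targets)
  c(single = min(da[1L], db[1L]),
    jointA = max(da[2L], db[2L]),
    jointB = max(da[3L], db[3L]))
}

# Weighted argmin of the choice rule: single weighted by (1 - w), joints by
# w. Ties broken by the smaller unweighted relevant distance, then by the
# fixed kind order single < jointA < jointB.
weighted_argmin <- function(d, w) {
  wd <- c(d[1L] * (1 - w), d[2L] * w, d[3L] * w)
  cand <- which(wd <= min(wd) + 1e-12)
  if (length(cand) > 1L)
    cand <- cand[order(d[cand], cand)]
  unname(cand[1L])
}

#' Weighted distance-based target choice
#'
#' Implements the dyad's preference-weighted path-minimization rule: the
#' chosen target minimizes the relevant distance weighted by `1 - w` for the
#' single target and `w` for either joint target. `w = 0.5` reduces to
#' plain closest-target choice; `w = 1` always selects the single target,
#' `w = 0` always a joint target. With probability `lapse_p` the rule is
#' ignored and a target is drawn uniformly.
#'
#' @param targets 3 x 2 matrix of target centres (kind order single, jointA,
#'   jointB).
#' @param pos_a,pos_b Agent positions at the start of the cycle.
#' @param w Weight in `[0, 1]` encoding single- vs joint-target preference.
#' @param lapse_p Probability of a uniform random choice instead of the rule.
#' @return Integer 1..3, the index of the chosen target kind.
#' @export
choose_target_weighted <- function(targets, pos_a, pos_b, w, lapse_p = 0) {
  stopifnot(w >= 0, w <= 1, lapse_p >= 0, lapse_p <= 1)
  if (lapse_p > 0 && runif(1) < lapse_p)
    return(sample.int(3L, 1L))
  weighted_argmin(layout_distances(pos_a, pos_b, targets), w)
}

#' Policy parameters of a synthetic agent
#'
#' @param w Weighted-choice preference in `[0, 1]` (0 fully cooperative,
#'   1 fully competitive).
#' @param lapse_p Probability of ignoring the weighted rule and choosing a
#'   target uniformly.
#' @param placement_mode What the free (non-collecting) agent does during a
#'   single-target collection: `"none"` (stay), `"advantageous"` (minimize
#'   the dyad's expected distance to the next single target, subject to the
#'   joint-target proximity constraint), `"competitive"` (maximize the
#'   probability of being closer than the collector to the next single
#'   target), `"invite"` (move onto the nearer joint target and stay,
#'   soliciting a cooperative next cycle), or `"split_field"` (each agent
#'   owns the half-field containing it; singles are collected by the owner).
#' @param speed_factor Multiplier `(0, 1]` of the speed cap; models skill.
#' @param reaction_delay Mean delay before movement onset at cycle start (s).
#' @param reaction_jitter Width (s) of a uniform per-cycle jitter added to
#'   the reaction delay; with jitter, small delay differences translate into
#'   graded (rather than near-deterministic) contested-race win rates.
#' @param turn_taking If `TRUE` (and set for both agents) the dyad strictly
#'   alternates between the two joint targets regardless of distance.
#' @param race_skill Competitive skill in `[0, 1]` (default 0.5). When both
#'   agents race for the single target, the probability that this agent wins
#'   is `0.5 + (race_skill - partner's race_skill) / 2`: the dyad's planted
#'   competitive skill difference is exactly the difference of the two
#'   `race_skill` values, expressed identically at every FST. The designated
#'   loser pulls up at the target rim, so the trajectories remain physical.
#'   With equal skills the race is decided purely by the kinematics
#'   (distances, speeds, reaction delays).
#' @param hover_drift Standard deviation (cm) of the small random
#'   repositioning an agent performs during the 1-s collection hover
#'   (cursor drift): collectors drift within the target radius, free
#'   agents drift freely. Prevents the artificial exactly-co-located cycle
#'   starts a point-mass simulation would otherwise produce after joint
#'   collections.
#' @param invite_accept Probability that this agent accepts a standing
#'   invitation by the partner.
#' @param miscoord_p Probability that the two agents draw their targets
#'   independently instead of the shared dyad-level draw (generates
#'   miscoordinated "different targets" and curved cycles).
#' @return An object of class `ccf_policy`.
#' @export
policy_params <- function(w = 0.5, lapse_p = 0,
                          placement_mode = c("none", "advantageous",
                                             "competitive", "invite",
                                             "split_field"),
                          speed_factor = 1, reaction_delay = 0,
                          reaction_jitter = 0, race_skill = 0.5,
                          hover_drift = 3,
                          turn_taking = FALSE, invite_accept = 0.8,
                          miscoord_p = 0) {
  placement_mode <- match.arg(placement_mode)
  stopifnot(w >= 0, w <= 1, lapse_p >= 0, lapse_p <= 1,
            speed_factor > 0, speed_factor <= 1, reaction_delay >= 0,
            reaction_jitter >= 0, race_skill >= 0, race_skill <= 1,
            hover_drift >= 0,
            invite_accept >= 0, invite_accept <= 1,
            miscoord_p >= 0, miscoord_p <= 1)
  structure(list(w = w, lapse_p = lapse_p, placement_mode = placement_mode,
                 speed_factor = speed_factor, reaction_delay = reaction_delay,
                 reaction_jitter = reaction_jitter, race_skill = race_skill,
                 hover_drift = hover_drift,
                 turn_taking = turn_taking, invite_accept = invite_accept,
                 miscoord_p = miscoord_p),
            class = "ccf_policy")
}

#' Precompute the placement landscape machinery
#'
#' Builds the candidate grid and the Monte-Carlo sample of future
#' single-target positions used by [advantageous_placement()], together with
#' a memoization environment keyed by the collector cell. The expected
#' distance surface varies smoothly with the collector position, so
#' landscapes are cached on a coarser collector grid (`snap`) and reused.
#'
#' @param config A [game_config()].
#' @param n_samples Monte-Carlo sample size for the expectation over the
#'   next single-target position (uniform over the admissible region).
#' @param seed Seed for the fixed Monte-Carlo sample.
#' @param grid_step Candidate grid resolution (cm).
#' @param snap Collector-cell snapping resolution for the cache (cm).
#' @return An object of class `ccf_placement_cache`.
#' @export
placement_cache <- function(config, n_samples = 2000, seed = 1,
                            grid_step = 1, snap = 3) {
  stopifnot(inherits(config, "ccf_config"), n_samples >= 100)
  side <- config$field_side
  gx <- seq(0, side, by = grid_step)
  grid <- as.matrix(expand.grid(x = gx, y = gx))
  r <- config$target_radius
  samples <- with_seed(child_seed(seed, 77L), {
    matrix(runif(2L * n_samples, min = r, max = side - r), ncol = 2L)
  })
  # Distances from every candidate grid point to every sampled future target.
  dgs <- sqrt(outer(grid[, 1L], samples[, 1L], "-")^2 +
              outer(grid[, 2L], samples[, 2L], "-")^2)
  structure(list(config = config, grid = grid, samples = samples, dgs = dgs,
                 grid_step = grid_step, snap = snap,
                 store = new.env(parent = emptyenv())),
            class = "ccf_placement_cache")
}

# Objective vector over the candidate grid for a given collector position.
placement_objective <- function(cache, collector, mode) {
  snap <- cache$snap
  side <- cache$config$field_side
  cs <- pmin(pmax(round(collector / snap) * snap, 0), side)
  key <- paste(mode, cs[1L], cs[2L], sep = "_")
  obj <- cache$store[[key]]
  if (is.null(obj)) {
    dc <- dist_to(cs, cache$samples)
    dcm <- matrix(dc, nrow = nrow(cache$dgs), ncol = length(dc), byrow = TRUE)
    obj <- if (mode == "competitive")
      rowMeans(cache$dgs < dcm)
    else
      rowMeans(pmin(cache$dgs, dcm))
    cache$store[[key]] <- obj
  }
  obj
}

#' Optimal free-agent placement during a single-target collection
#'
#' While one agent collects the single target, the free agent can move to a
#' starting position for the next cycle. In `"advantageous"` mode the
#' returned point minimizes the expected distance from *either* agent to the
#' next uniformly placed single target, restricted to points no farther from
#' the joint target nearest the collector than the collector itself (so a
#' subsequent joint collection is not delayed). In `"competitive"` mode it
#' maximizes the probability of being strictly closer than the collector to
#' the next single target (no proximity constraint), which lands just beside
#' the collector on the field-centre side.
#'
#' @param collector Collector position (the single target being collected).
#' @param joints 2 x 2 matrix of the two joint-target centres (rows jointA,
#'   jointB).
#' @param mode `"advantageous"` or `"competitive"`.
#' @param cache A [placement_cache()].
#' @return Length-2 position (cm) with attributes `objective` (the achieved
#'   objective value) and `feasible_n` (number of feasible grid points).
#' @export
advantageous_placement <- function(collector, joints,
                                   mode = c("advantageous", "competitive"),
                                   cache) {
  mode <- match.arg(mode)
  stopifnot(inherits(cache, "ccf_placement_cache"))
  obj <- placement_objective(cache, collector, mode)
  grid <- cache$grid
  if (mode == "advantageous") {
    dj <- c(dist2(collector, joints[1L, ]), dist2(collector, joints[2L, ]))
    jstar <- joints[which.min(dj), ]
    feasible <- dist_to(jstar, grid) <= min(dj) + 1e-9
    if (!any(feasible)) {
      warning("empty feasible placement set; falling back to a collector-adjacent point")
      i <- which.min(dist_to(collector, grid))
      p <- grid[i, ]
      attr(p, "objective") <- obj[i]
      attr(p, "feasible_n") <- 0L
      return(p)
    }
    idx <- which(feasible)
    i <- idx[which.min(obj[idx])]
    n_feas <- length(idx)
  } else {
    i <- which.max(obj)
    n_feas <- nrow(grid)
  }
  p <- grid[i, ]
  attr(p, "objective") <- obj[i]
  attr(p, "feasible_n") <- n_feas
  p
}
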