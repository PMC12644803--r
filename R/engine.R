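# Game engine: field, targets, capped movement, hover collection, payoffs,
# respawn. The state is a plain list; all randomness (spawns, tie-breaks)
# flows through the RNG state carried inside it, so a session is fully
# determined by (seed, commanded-velocity stream).

# Run `code` with the RNG positioned at `state$rng_state`; store the advanced
# RNG state back. Returns list(value, state).
use_state_rng <- function(state, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  }
  assign(".Random.seed", state$rng_state, envir = globalenv())
  value <- code
  state$rng_state <- get(".Random.seed", envir = globalenv())
  list(value = value, state = state)
}

#' Initialize a game session
#'
#' Places one single and two joint targets uniformly at random without
#' overlap, and both agents uniformly on the field. The same seed always
#' yields the identical state.
#'
#' @param config A [game_config()] object.
#' @param seed Integer seed.
#' @return A game state: a list with elements `time`, `tick`, `pos` (2 x 2
#'   matrix, rows agents A and B), `targets` (3 x 2 matrix, rows in the fixed
#'   kind order single, jointA, jointB), `target_ids`, `progress` (per-target
#'   hover progress in seconds), `single_claimant` (1, 2 or `NA`), `payoffs`
#'   (cumulative cents for A and B), `n_events`, and an opaque `rng_state`.
#' @export
init_session <- function(config, seed) {
  stopifnot(inherits(config, "ccf_config"))
  state <- with_seed(child_seed(seed, 1L), {
    targets <- matrix(NA_real_, 3, 2,
                      dimnames = list(TARGET_KINDS, c("x", "y")))
    for (i in 1:3)
      targets[i, ] <- sample_nonoverlapping(config, targets[seq_len(i - 1L), , drop = FALSE])
    pos <- matrix(runif(4, 0, config$field_side), 2, 2, byrow = TRUE,
                  dimnames = list(c("A", "B"), c("x", "y")))
    list(
      config = config,
      time = 0,
      tick = 0L,
      pos = pos,
      targets = targets,
      target_ids = 1:3,
      next_id = 4L,
      progress = c(single = 0, jointA = 0, jointB = 0),
      joint_occupied = c(jointA = FALSE, jointB = FALSE),
      single_claimant = NA_integer_,
      payoffs = c(A = 0, B = 0),
      n_events = 0L,
      rng_state = get(".Random.seed", envir = globalenv())
    )
  })
  state
}

#' Advance the game by one tick
#'
#' Applies commanded velocities (clipped to the speed cap, direction
#' preserved), clamps positions to the field, and updates hover progress:
#' a single target accrues progress while its claimant (the first agent to
#' occupy it) stays within the target radius; a joint target accrues progress
#' only while both agents are inside; leaving before completion resets that
#' target's progress to zero. Simultaneous same-tick arrival at the single
#' target is broken by a seeded coin flip.
#'
#' @param state Game state from [init_session()] or a previous step.
#' @param vel 2 x 2 matrix of commanded velocities (cm/s), rows agents A, B.
#' @param dt Tick duration (s); must equal `1 / tick_rate`.
#' @return The updated state. Check [completed_target()] afterwards and call
#'   [resolve_collection()] when a target's hover completes.
#' @export
step_game <- function(state, vel, dt = state$config$dt) {
  cfg <- state$config
  if (abs(dt - cfg$dt) > 1e-12)
    stop("`dt` must equal 1 / tick_rate", call. = FALSE)
  vel <- matrix(as.numeric(vel), 2, 2)
  if (any(!is.finite(vel)))
    stop("non-finite commanded velocity", call. = FALSE)

  speeds <- sqrt(rowSums(vel^2))
  over <- speeds > cfg$max_speed
  if (any(over))
    vel[over, ] <- vel[over, , drop = FALSE] * (cfg$max_speed / speeds[over])

  pos <- state$pos + vel * dt
  pos[] <- pmin(pmax(pos, 0), cfg$field_side)
  state$pos <- pos

  r <- cfg$target_radius
  inside <- matrix(FALSE, 2, 3)  # agents x targets
  for (j in 1:3)
    inside[, j] <- dist_to(state$targets[j, ], pos) <= r

  # Single target: claimant-based progress. The entry tick establishes the
  # claim; progress accrues on subsequent ticks, so a collection completes
  # exactly `hover_time` after entry.
  claimant <- state$single_claimant
  if (!is.na(claimant)) {
    if (inside[claimant, 1L]) {
      state$progress[1L] <- state$progress[1L] + dt
    } else {
      claimant <- NA_integer_
      state$progress[1L] <- 0
    }
  }
  if (is.na(claimant)) {
    state$progress[1L] <- 0
    if (inside[1L, 1L] && inside[2L, 1L]) {
      res <- use_state_rng(state, sample.int(2L, 1L))
      state <- res$state
      claimant <- res$value
    } else if (inside[1L, 1L]) claimant <- 1L
    else if (inside[2L, 1L]) claimant <- 2L
  }
  state$single_claimant <- claimant

  # Joint targets: both agents must be inside simultaneously; progress
  # accrues from the tick after joint occupancy is established.
  for (j in 2:3) {
    occ <- inside[1L, j] && inside[2L, j]
    if (occ && state$joint_occupied[j - 1L])
      state$progress[j] <- state$progress[j] + dt
    else
      state$progress[j] <- 0
    state$joint_occupied[j - 1L] <- occ
  }

  state$tick <- state$tick + 1L
  state$time <- state$tick * cfg$dt
  state
}

#' Index of a completed target, if any
#'
#' @param state Game state.
#' @return Integer index (1 = single, 2 = jointA, 3 = jointB) of the target
#'   whose hover progress has reached `hover_time`, or `integer(0)`.
#' @export
completed_target <- function(state) {
  unname(which(state$progress >= state$config$hover_time - 1e-9))
}

#' Resolve a completed collection
#'
#' Records the collection event, credits payoffs (single: all
#' `payoff_single` cents to the claimant; joint: major/minor split by which
#' agent the target favours), and respawns the collected target uniformly at
#' random without overlap. The agents and the two uncollected targets are not
#' moved, giving a continuous transition into the next cycle.
#'
#' @param state Game state with a completed target.
#' @return `list(event, state)`. The event records the event index, target
#'   kind/id/position, collector (`"A"`, `"B"` or `"both"`), the collection
#'   start and end times, and both payoffs (cents).
#' @export
resolve_collection <- function(state) {
  cfg <- state$config
  idx <- completed_target(state)
  if (length(idx) == 0L)
    stop("resolve_collection() called with no completed target", call. = FALSE)
  idx <- idx[1L]
  kind <- TARGET_KINDS[idx]

  if (kind == "single") {
    collector <- c("A", "B")[state$single_claimant]
    pay <- if (collector == "A") c(cfg$payoff_single, 0) else c(0, cfg$payoff_single)
  } else if (kind == "jointA") {
    collector <- "both"
    pay <- c(cfg$payoff_joint_major, cfg$payoff_joint_minor)
  } else {
    collector <- "both"
    pay <- c(cfg$payoff_joint_minor, cfg$payoff_joint_major)
  }

  event <- list(
    index = state$n_events + 1L,
    kind = kind,
    id = state$target_ids[idx],
    position = state$targets[idx, ],
    collector = collector,
    t_collect_start = state$time - cfg$hover_time,
    t_end = state$time,
    payoff_a = pay[1L],
    payoff_b = pay[2L]
  )

  res <- use_state_rng(state, sample_nonoverlapping(
    cfg, state$targets[-idx, , drop = FALSE]))
  state <- res$state
  state$targets[idx, ] <- res$value
  state$target_ids[idx] <- state$next_id
  state$next_id <- state$next_id + 1L
  state$progress[idx] <- 0
  if (idx == 1L) state$single_claimant <- NA_integer_
  else state$joint_occupied[idx - 1L] <- FALSE
  state$payoffs <- state$payoffs + pay
  state$n_events <- state$n_events + 1L

  list(event = event, state = state)
}
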