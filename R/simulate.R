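# Synthetic dyad simulation. Policies move along piecewise-linear legs
# (straight pursuit at a capped speed after a reaction delay), so a session
# can be simulated event-by-event and the 120 Hz trajectories materialized
# by interpolation. The per-tick engine (`step_game()`) defines the rules;
# the test suite replays simulated velocity streams through it to confirm
# both paths agree tick for tick.

# -- trajectory recorder -----------------------------------------------------

new_recorder <- function() {
  env <- new.env(parent = emptyenv())
  env$segs <- list(A = vector("list", 256L), B = vector("list", 256L))
  env$n <- c(A = 0L, B = 0L)
  env$tick <- c(A = 0L, B = 0L)
  env$pos <- list(A = NULL, B = NULL)
  env
}

rec_init <- function(rec, agent, pos) {
  rec$pos[[agent]] <- pos
  rec$tick[agent] <- 0L
}

# Append a linear segment for `agent` from its cursor to (tick1, pos1).
rec_add <- function(rec, agent, tick1, pos1) {
  t0 <- rec$tick[agent]
  if (tick1 < t0) stop("segment ends before cursor", call. = FALSE)
  if (tick1 == t0) { rec$pos[[agent]] <- pos1; return(invisible()) }
  n <- rec$n[agent] + 1L
  if (n > length(rec$segs[[agent]]))
    rec$segs[[agent]] <- c(rec$segs[[agent]], vector("list", length(rec$segs[[agent]])))
  rec$segs[[agent]][[n]] <- c(t0, tick1, rec$pos[[agent]], pos1)
  rec$n[agent] <- n
  rec$tick[agent] <- tick1
  rec$pos[[agent]] <- pos1
  invisible()
}

rec_hold <- function(rec, agent, tick1) rec_add(rec, agent, tick1, rec$pos[[agent]])

# Materialize one agent's positions at ticks 0..t_end.
rec_positions <- function(rec, agent, t_end) {
  out <- matrix(NA_real_, t_end + 1L, 2L)
  segs <- rec$segs[[agent]][seq_len(rec$n[agent])]
  if (rec$n[agent] == 0L) {
    out[, 1L] <- rec$pos[[agent]][1L]; out[, 2L] <- rec$pos[[agent]][2L]
    return(out)
  }
  first <- segs[[1L]]
  out[1L, ] <- first[3:4]
  for (s in segs) {
    idx <- (s[1L] + 1L):s[2L]
    f <- (idx - s[1L]) / (s[2L] - s[1L])
    out[idx + 1L, 1L] <- s[3L] + f * (s[5L] - s[3L])
    out[idx + 1L, 2L] <- s[4L] + f * (s[6L] - s[4L])
  }
  if (rec$tick[agent] < t_end) {
    idx <- (rec$tick[agent] + 1L):t_end
    out[idx + 1L, 1L] <- rec$pos[[agent]][1L]
    out[idx + 1L, 2L] <- rec$pos[[agent]][2L]
  }
  out
}

# Travel in a straight line from the agent's cursor toward `goal`, stopping
# once within `rstop` of it (or at `stop_tick`). Returns the arrival tick or
# NA when truncated.
rec_travel <- function(rec, agent, goal, step, rstop, stop_tick = Inf) {
  p0 <- rec$pos[[agent]]
  t0 <- rec$tick[agent]
  d <- dist2(p0, goal)
  if (d <= rstop) return(t0)
  n <- as.integer(ceiling((d - rstop) / step - 1e-9))
  u <- (goal - p0) / d
  if (t0 + n <= stop_tick) {
    travelled <- min(n * step, d)
    rec_add(rec, agent, t0 + n, p0 + u * travelled)
    return(t0 + n)
  }
  k <- stop_tick - t0
  if (k > 0L) rec_add(rec, agent, stop_tick, p0 + u * min(k * step, d))
  NA_integer_
}

# -- session simulation ------------------------------------------------------

#' Simulate a dyad session
#'
#' Runs `n_cycles` collection cycles of the foraging game under two agent
#' policies ([policy_params()]). Each cycle the dyad chooses a target by the
#' weighted distance rule (a shared draw, or independent draws with
#' probability `miscoord_p`, producing miscoordinated cycles), the agents
#' move straight toward their goals at `speed_factor * max_speed` after
#' `reaction_delay`, hover for 1 s to collect, and the collected target
#' respawns. Free-agent behaviour during single-target collections follows
#' each policy's `placement_mode`; an agent left standing on a joint target
#' constitutes an invitation the partner accepts with its `invite_accept`
#' probability. With `turn_taking` set for both agents the dyad strictly
#' alternates the two joint targets.
#'
#' @param config A [game_config()].
#' @param params_a,params_b Policies for agents A and B.
#' @param n_cycles Number of collection cycles to simulate.
#' @param seed Integer seed; a seed fully determines the session.
#' @param cache Optional [placement_cache()] (built on demand when a policy
#'   uses a placement optimizer).
#' @return A `ccf_session`: list with `positions` (data frame `t_s, ax_cm,
#'   ay_cm, bx_cm, by_cm`, one row per 120 Hz tick), `events` (one row per
#'   collection: cycle, timing, target kind and position, the full target
#'   layout at cycle start, collector, payoffs), `config`, and `seed`.
#' @export
simulate_dyad <- function(config, params_a, params_b, n_cycles, seed,
                          cache = NULL) {
  stopifnot(inherits(config, "ccf_config"),
            inherits(params_a, "ccf_policy"), inherits(params_b, "ccf_policy"),
            n_cycles >= 1)
  needs_cache <- any(c(params_a$placement_mode, params_b$placement_mode) %in%
                       c("advantageous", "competitive"))
  if (needs_cache && is.null(cache))
    cache <- placement_cache(config, seed = child_seed(seed, 3L))

  with_seed(child_seed(seed, 2L), {
    simulate_dyad_impl(config, params_a, params_b, n_cycles, seed, cache)
  })
}

simulate_dyad_impl <- function(config, pa, pb, n_cycles, seed, cache) {
  r <- config$target_radius
  dt <- config$dt
  hover_ticks <- config$hover_ticks
  par <- list(A = pa, B = pb)
  step_of <- c(A = pa$speed_factor * config$max_speed * dt,
               B = pb$speed_factor * config$max_speed * dt)
  jitter_of <- c(A = pa$reaction_jitter, B = pb$reaction_jitter)
  base_delay <- c(A = pa$reaction_delay, B = pb$reaction_delay)
  # per-cycle reaction delays (ticks); redrawn at each cycle start
  delay_of <- c(A = 0L, B = 0L)
  draw_delays <- function() {
    d <- base_delay + runif(2L) * jitter_of
    c(A = as.integer(round(d[1L] * config$tick_rate)),
      B = as.integer(round(d[2L] * config$tick_rate)))
  }
  turn_taking <- isTRUE(pa$turn_taking) && isTRUE(pb$turn_taking)
  w_dyad <- mean(c(pa$w, pb$w))
  lapse_dyad <- mean(c(pa$lapse_p, pb$lapse_p))
  miscoord <- mean(c(pa$miscoord_p, pb$miscoord_p))
  yield_ticks <- as.integer(round(0.5 * config$tick_rate))
  race_bias <- pa$race_skill - pb$race_skill

  # Initial layout and positions (same law as init_session).
  targets <- matrix(NA_real_, 3, 2, dimnames = list(TARGET_KINDS, c("x", "y")))
  for (i in 1:3)
    targets[i, ] <- sample_nonoverlapping(config, targets[seq_len(i - 1L), , drop = FALSE])
  pos <- list(A = runif(2, 0, config$field_side),
              B = runif(2, 0, config$field_side))

  rec <- new_recorder()
  rec_init(rec, "A", pos$A)
  rec_init(rec, "B", pos$B)

  events <- vector("list", n_cycles)
  next_joint <- 2L  # turn-taking alternation state
  t0 <- 0L          # cycle start tick

  arrival_ticks <- function(agent, goal, start_tick) {
    p <- rec$pos[[agent]]
    d <- dist2(p, goal)
    # an agent already on the target occupies it from the first tick of the
    # cycle; reaction delay applies only to movement
    if (d <= r) return(start_tick + 1L)
    trav <- as.integer(ceiling((d - r) / step_of[agent] - 1e-9))
    start_tick + delay_of[agent] + trav
  }

  go <- function(agent, goal, start_tick, stop_tick = Inf, rstop = r) {
    # reaction delay, then straight travel
    rec_hold(rec, agent, min(start_tick + delay_of[agent], stop_tick))
    rec_travel(rec, agent, goal, step_of[agent], rstop, stop_tick)
  }

  # Small repositioning during the hover: collectors drift to a random
  # point inside the target (the path of two points in a disk stays inside
  # it, so occupancy is never broken); free agents drift freely. Keeps
  # cycle-start positions from collapsing onto exact points.
  drift_disk <- function(agent, center, end_tick) {
    if (par[[agent]]$hover_drift > 0) {
      ang <- runif(1) * 2 * pi
      rad <- sqrt(runif(1)) * (r - 0.5)
      rec_travel(rec, agent, center + rad * c(cos(ang), sin(ang)),
                 step_of[agent], 0, end_tick)
    }
    rec_hold(rec, agent, end_tick)
  }
  drift_free <- function(agent, end_tick) {
    ds <- par[[agent]]$hover_drift
    if (ds > 0) {
      # avoid drifting onto a target: parking there would read as an
      # (unintended) invitation or an instant claim next cycle
      for (try in 1:8) {
        goal <- pmin(pmax(rec$pos[[agent]] + stats::rnorm(2L, 0, ds), 0),
                     config$field_side)
        if (all(dist_to(goal, targets) > r + 0.3)) {
          rec_travel(rec, agent, goal, step_of[agent], 0, end_tick)
          break
        }
      }
    }
    rec_hold(rec, agent, end_tick)
  }

  free_agent_behaviour <- function(agent, start_tick, end_tick, single_pos) {
    mode <- par[[agent]]$placement_mode
    if (mode %in% c("advantageous", "competitive")) {
      pnt <- advantageous_placement(single_pos, targets[2:3, , drop = FALSE],
                                    mode, cache)
      go(agent, as.numeric(pnt), start_tick, end_tick, rstop = 0)
      rec_hold(rec, agent, end_tick)
    } else if (mode == "invite") {
      j <- if (dist2(rec$pos[[agent]], targets[2L, ]) <=
               dist2(rec$pos[[agent]], targets[3L, ])) 2L else 3L
      go(agent, targets[j, ], start_tick, end_tick, rstop = r - 0.5)
      rec_hold(rec, agent, end_tick)
    } else {
      drift_free(agent, end_tick)
    }
  }

  for (cyc in seq_len(n_cycles)) {
    start_pos <- list(A = rec$pos[["A"]], B = rec$pos[["B"]])
    layout <- targets
    delay_of <- draw_delays()

    # Standing invitation: exactly-one agent sitting on a joint target.
    on_joint <- c(A = NA_integer_, B = NA_integer_)
    for (ag in c("A", "B")) {
      dj <- dist_to(rec$pos[[ag]], targets[2:3, , drop = FALSE])
      if (min(dj) <= r) on_joint[ag] <- which.min(dj) + 1L
    }
    inviter <- NA_character_
    if (!turn_taking && xor(!is.na(on_joint["A"]), !is.na(on_joint["B"])))
      inviter <- if (!is.na(on_joint["A"])) "A" else "B"

    scenario <- NULL
    if (!is.na(inviter)) {
      partner <- setdiff(c("A", "B"), inviter)
      j <- on_joint[inviter]
      if (runif(1) < par[[partner]]$invite_accept)
        scenario <- list(type = "joint", j = j, sitter = inviter)
      else
        scenario <- list(type = "split", single_goer = partner,
                         joint_sitter = inviter, sitter_j = j)
    } else if (turn_taking) {
      scenario <- list(type = "joint", j = next_joint, sitter = NULL)
      next_joint <- if (next_joint == 2L) 3L else 2L
    } else {
      if (miscoord > 0 && runif(1) < miscoord) {
        cA <- choose_target_weighted(targets, rec$pos[["A"]], rec$pos[["B"]],
                                     pa$w, pa$lapse_p)
        cB <- choose_target_weighted(targets, rec$pos[["A"]], rec$pos[["B"]],
                                     pb$w, pb$lapse_p)
      } else {
        cA <- cB <- choose_target_weighted(targets, rec$pos[["A"]],
                                           rec$pos[["B"]], w_dyad, lapse_dyad)
      }
      if (cA == cB) {
        scenario <- if (cA == 1L) list(type = "single")
                    else list(type = "joint", j = cA, sitter = NULL)
      } else if (cA == 1L || cB == 1L) {
        scenario <- list(type = "split",
                         single_goer = if (cA == 1L) "A" else "B",
                         joint_goer = if (cA == 1L) "B" else "A",
                         goer_j = max(cA, cB))
      } else {
        scenario <- list(type = "deadlock", jA = cA, jB = cB)
      }
    }

    if (scenario$type == "joint") {
      j <- scenario$j
      goal <- targets[j, ]
      arr <- c(A = if (identical(scenario$sitter, "A")) t0 else arrival_ticks("A", goal, t0),
               B = if (identical(scenario$sitter, "B")) t0 else arrival_ticks("B", goal, t0))
      m <- max(arr)
      end_tick <- m + hover_ticks
      for (ag in c("A", "B")) {
        if (!identical(scenario$sitter, ag)) go(ag, goal, t0)
        drift_disk(ag, goal, end_tick)
      }
      kind <- TARGET_KINDS[j]
      collector <- "both"
      t_collect <- m * dt
      collected <- j
    } else if (scenario$type == "single") {
      goal <- targets[1L, ]
      # Which agents race? Placement policies leave the race to the closer
      # agent; split-field assigns the owner of the single's half.
      modes <- c(A = pa$placement_mode, B = pb$placement_mode)
      dA <- dist2(rec$pos[["A"]], goal); dB <- dist2(rec$pos[["B"]], goal)
      closer <- if (dA <= dB) "A" else "B"
      if (modes[["A"]] == "split_field" && modes[["B"]] == "split_field") {
        half <- config$field_side / 2
        ownA <- (rec$pos[["A"]][1L] < half) == (goal[1L] < half)
        ownB <- (rec$pos[["B"]][1L] < half) == (goal[1L] < half)
        racers <- if (ownA && !ownB) "A" else if (ownB && !ownA) "B" else closer
      } else {
        racers <- c("A", "B")
        for (ag in c("A", "B"))
          if (modes[[ag]] %in% c("advantageous", "competitive", "invite") &&
              ag != closer)
            racers <- setdiff(racers, ag)
      }
      arr <- vapply(racers, arrival_ticks, integer(1L), goal = goal,
                    start_tick = t0)
      if (length(racers) == 2L && race_bias != 0) {
        # planted competitive skill: a biased coin decides the contested
        # race. The designated winner sheds reaction delay as needed so the
        # claim still happens at the kinematically earliest arrival (skill
        # shows as faster reactions, not slower cycles); the designated
        # loser pulls up at the target rim.
        winner <- if (runif(1) < (1 + race_bias) / 2) "A" else "B"
        deficit <- arr[[winner]] - min(arr)
        if (deficit > 0L) {
          delay_of[winner] <- max(0L, delay_of[winner] - deficit)
          arr[[winner]] <- arrival_ticks(winner, goal, t0)
        }
        claim <- arr[[winner]]
      } else {
        winner <- racers[which(arr == min(arr))]
        if (length(winner) > 1L) winner <- winner[sample.int(length(winner), 1L)]
        claim <- min(arr)
      }
      end_tick <- claim + hover_ticks
      go(winner, goal, t0)
      drift_disk(winner, goal, end_tick)
      loser_rstop <- if (length(racers) == 2L && race_bias != 0) r + 0.4 else r
      for (ag in setdiff(c("A", "B"), winner)) {
        if (ag %in% racers) {
          # frozen when the claim starts (or at the rim, under planted skill)
          go(ag, goal, t0, stop_tick = claim, rstop = loser_rstop)
          free_agent_behaviour(ag, claim, end_tick, goal)
        } else {
          free_agent_behaviour(ag, t0, end_tick, goal)
        }
      }
      kind <- "single"
      collector <- winner
      t_collect <- claim * dt
      collected <- 1L
    } else if (scenario$type == "split") {
      sg <- scenario$single_goer
      goal <- targets[1L, ]
      claim <- arrival_ticks(sg, goal, t0)
      end_tick <- claim + hover_ticks
      go(sg, goal, t0)
      drift_disk(sg, goal, end_tick)
      other <- setdiff(c("A", "B"), sg)
      if (!is.null(scenario$joint_sitter)) {
        rec_hold(rec, other, end_tick)  # keeps dwelling on its joint
      } else {
        go(other, targets[scenario$goer_j, ], t0, stop_tick = end_tick,
           rstop = r - 0.5)
        rec_hold(rec, other, end_tick)
      }
      kind <- "single"
      collector <- sg
      t_collect <- claim * dt
      collected <- 1L
    } else {  # deadlock: A and B head to different joint targets
      arrA <- arrival_ticks("A", targets[scenario$jA, ], t0)
      arrB <- arrival_ticks("B", targets[scenario$jB, ], t0)
      go("A", targets[scenario$jA, ], t0)
      go("B", targets[scenario$jB, ], t0)
      yielder <- c("A", "B")[sample.int(2L, 1L)]
      stayer <- setdiff(c("A", "B"), yielder)
      j <- if (stayer == "A") scenario$jA else scenario$jB
      yield_from <- max(arrA, arrB) + yield_ticks
      rec_hold(rec, yielder, yield_from)
      ya <- rec_travel(rec, yielder, targets[j, ], step_of[yielder], r)
      stayer_arr <- if (stayer == "A") arrA else arrB
      m <- max(ya, stayer_arr)
      end_tick <- m + hover_ticks
      drift_disk("A", targets[j, ], end_tick)
      drift_disk("B", targets[j, ], end_tick)
      kind <- TARGET_KINDS[j]
      collector <- "both"
      t_collect <- m * dt
      collected <- j
    }

    if (kind == "single") {
      pay <- if (collector == "A") c(config$payoff_single, 0) else c(0, config$payoff_single)
    } else if (kind == "jointA") {
      pay <- c(config$payoff_joint_major, config$payoff_joint_minor)
    } else {
      pay <- c(config$payoff_joint_minor, config$payoff_joint_major)
    }

    events[[cyc]] <- data.frame(
      cycle = cyc,
      t_cycle_start_s = t0 * dt,
      t_collect_start_s = t_collect,
      t_end_s = end_tick * dt,
      target_kind = kind,
      target_x_cm = targets[collected, 1L],
      target_y_cm = targets[collected, 2L],
      single_x_cm = layout[1L, 1L], single_y_cm = layout[1L, 2L],
      jointA_x_cm = layout[2L, 1L], jointA_y_cm = layout[2L, 2L],
      jointB_x_cm = layout[3L, 1L], jointB_y_cm = layout[3L, 2L],
      collector = collector,
      payoff_a_cents = pay[1L],
      payoff_b_cents = pay[2L],
      stringsAsFactors = FALSE
    )

    targets[collected, ] <- sample_nonoverlapping(
      config, targets[-collected, , drop = FALSE])
    t0 <- end_tick
  }

  t_end <- t0
  posA <- rec_positions(rec, "A", t_end)
  posB <- rec_positions(rec, "B", t_end)
  positions <- data.frame(
    t_s = (0:t_end) * dt,
    ax_cm = posA[, 1L], ay_cm = posA[, 2L],
    bx_cm = posB[, 1L], by_cm = posB[, 2L]
  )
  structure(list(positions = positions,
                 events = do.call(rbind, events),
                 config = config, seed = seed),
            class = "ccf_session")
}

#' @export
print.ccf_session <- function(x, ...) {
  n <- nrow(x$events)
  fst <- mean(x$events$target_kind == "single")
  cat("<ccf_session> ", n, " collection cycles over ",
      round(max(x$positions$t_s), 1), " s; FST ", round(fst, 3),
      "; payoffs A ", sum(x$events$payoff_a_cents), " / B ",
      sum(x$events$payoff_b_cents), " cents\n", sep = "")
  invisible(x)
}
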