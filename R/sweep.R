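# Strategy landscape: event-level simulation of idealized dyads (straight
# lines at the speed cap, choices by the weighted distance rule) across a
# grid of preference weights, with or without advantageous placement of the
# free agent during single-target collections.

sweep_one_w <- function(config, w, placement, follow_p, n_cycles, cache,
                        keep_cycles = FALSE) {
  r <- config$target_radius
  v <- config$max_speed
  lapse <- 1 - follow_p

  targets <- matrix(NA_real_, 3, 2, dimnames = list(TARGET_KINDS, c("x", "y")))
  for (i in 1:3)
    targets[i, ] <- sample_nonoverlapping(config, targets[seq_len(i - 1L), , drop = FALSE])
  # Idealized co-located start in the field centre.
  pos_a <- pos_b <- rep(config$field_side / 2, 2L)

  kinds <- character(n_cycles)
  dists <- durations <- numeric(n_cycles)
  cyc_rows <- if (keep_cycles) vector("list", n_cycles) else NULL
  t_clock <- 0

  for (cyc in seq_len(n_cycles)) {
    j <- choose_target_weighted(targets, pos_a, pos_b, w, lapse)
    d <- layout_distances(pos_a, pos_b, targets)
    d_rel <- d[j]
    duration <- d_rel / v + config$hover_time

    if (keep_cycles) {
      cyc_rows[[cyc]] <- c(t_clock, pos_a, pos_b, t(targets), j)
    }

    if (j == 1L) {
      da <- dist2(pos_a, targets[1L, ]); db <- dist2(pos_b, targets[1L, ])
      collector_is_a <- da <= db
      goal <- targets[1L, ]
      if (placement == "advantageous") {
        free_from <- if (collector_is_a) pos_b else pos_a
        pnt <- as.numeric(advantageous_placement(goal, targets[2:3, , drop = FALSE],
                                                 "advantageous", cache))
        # The free agent repositions during the whole cycle, speed-capped.
        budget <- duration * v
        dd <- dist2(free_from, pnt)
        free_to <- if (dd <= budget || dd < 1e-12) pnt
                   else free_from + (pnt - free_from) * (budget / dd)
        if (collector_is_a) { pos_a <- goal; pos_b <- free_to }
        else { pos_b <- goal; pos_a <- free_to }
      } else {
        pos_a <- pos_b <- goal  # co-located start of the next cycle
      }
    } else {
      pos_a <- pos_b <- targets[j, ]
    }

    kinds[cyc] <- TARGET_KINDS[j]
    dists[cyc] <- d_rel
    durations[cyc] <- duration
    t_clock <- t_clock + duration
    targets[j, ] <- sample_nonoverlapping(config, targets[-j, , drop = FALSE])
  }

  out <- list(
    fst = mean(kinds == "single"),
    mean_distance = mean(dists),
    payoff_rate = config$payoff_single * n_cycles / sum(durations)
  )
  if (keep_cycles) {
    m <- do.call(rbind, cyc_rows)
    cycles <- data.frame(
      cycle = seq_len(n_cycles),
      t_cycle_start_s = m[, 1L],
      ax_cm = m[, 2L], ay_cm = m[, 3L], bx_cm = m[, 4L], by_cm = m[, 5L],
      single_x_cm = m[, 6L], single_y_cm = m[, 7L],
      jointA_x_cm = m[, 8L], jointA_y_cm = m[, 9L],
      jointB_x_cm = m[, 10L], jointB_y_cm = m[, 11L],
      target_kind = TARGET_KINDS[m[, 12L]],
      stringsAsFactors = FALSE
    )
    cycles$prev1_kind <- c(NA, cycles$target_kind[-n_cycles])
    cycles$prev2_kind <- c(NA, NA, cycles$target_kind[-c(n_cycles - 1L, n_cycles)])
    out$cycles <- cycles
  }
  out
}

#' Sweep the preference weight and map the strategy landscape
#'
#' Simulates idealized dyads over a grid of choice weights `w` and records,
#' per grid point, the realized fraction of single targets (FST), the mean
#' relevant distance to the collected target, and the joint payoff rate.
#' With `placement = "none"` both agents share the collected target's
#' position at the start of every cycle (pure path minimization; the payoff
#' optimum falls at FST = 1/3). With `placement = "advantageous"` the free
#' agent repositions during single-target collections to minimize the
#' expected distance to the next single target under the joint-target
#' proximity constraint, which shifts the payoff-maximizing FST upward
#' (to about 0.55). `follow_p` < 1 makes the dyad follow the weighted rule
#' in only that fraction of cycles and choose uniformly otherwise.
#'
#' @param config A [game_config()].
#' @param w_grid Numeric vector of weights in `[0, 1]`.
#' @param placement `"none"` or `"advantageous"`.
#' @param follow_p Probability of following the weighted rule (e.g. 0.7,
#'   0.9, 1).
#' @param n_cycles Collection cycles simulated per grid point.
#' @param seed Integer seed; grid points get independent derived streams, so
#'   two sweeps with the same seed are comparable point by point.
#' @param cache Optional [placement_cache()]; built (and shared across the
#'   grid) when `placement = "advantageous"`.
#' @param keep_cycles If `TRUE`, attach per-cycle records (start positions,
#'   layout, outcome) for each grid point as attribute `"cycles"` (a list).
#' @return A data frame of class `ccf_sweep` with columns `w`, `fst`,
#'   `mean_distance_cm`, `payoff_rate` (cents/s).
#' @export
strategy_sweep <- function(config, w_grid = seq(0, 1, by = 0.05),
                           placement = c("none", "advantageous"),
                           follow_p = 1, n_cycles = 2000, seed = 1,
                           cache = NULL, keep_cycles = FALSE) {
  placement <- match.arg(placement)
  stopifnot(all(w_grid >= 0 & w_grid <= 1), follow_p >= 0, follow_p <= 1,
            n_cycles >= 1)
  if (placement == "advantageous" && is.null(cache))
    cache <- placement_cache(config, seed = child_seed(seed, 3L))

  res <- vector("list", length(w_grid))
  for (i in seq_along(w_grid)) {
    res[[i]] <- with_seed(child_seed(seed, 100L + i), {
      sweep_one_w(config, w_grid[i], placement, follow_p, n_cycles, cache,
                  keep_cycles)
    })
  }
  out <- data.frame(
    w = w_grid,
    fst = vapply(res, `[[`, numeric(1L), "fst"),
    mean_distance_cm = vapply(res, `[[`, numeric(1L), "mean_distance"),
    payoff_rate = vapply(res, `[[`, numeric(1L), "payoff_rate")
  )
  if (keep_cycles)
    attr(out, "cycles") <- lapply(res, `[[`, "cycles")
  class(out) <- c("ccf_sweep", "data.frame")
  out
}

#' FST at the payoff-rate maximum of a sweep
#'
#' The payoff landscape is nearly flat around its optimum, so the raw
#' per-grid-point argmax is dominated by Monte-Carlo noise. By default the
#' payoff-rate curve is therefore smoothed (local quadratic regression on
#' FST) and the maximum located on the smoothed curve; `smooth = FALSE`
#' returns the raw argmax.
#'
#' @param sweep A [strategy_sweep()] result.
#' @param smooth Smooth the payoff-vs-FST curve before locating the maximum.
#' @param span Loess span for the smoothing.
#' @return The FST value at the payoff-rate maximum.
#' @export
optimal_fst <- function(sweep, smooth = TRUE, span = 0.75) {
  stopifnot(inherits(sweep, "ccf_sweep"))
  if (!smooth || nrow(sweep) < 8L)
    return(sweep$fst[which.max(sweep$payoff_rate)])
  fit <- stats::loess(payoff_rate ~ fst, data = sweep, span = span,
                      degree = 2)
  grid <- seq(min(sweep$fst), max(sweep$fst), length.out = 401L)
  grid[which.max(stats::predict(fit, newdata = data.frame(fst = grid)))]
}
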