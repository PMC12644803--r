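# Session metrics: cycle segmentation, FST time courses, convergence and
# strategy groups.

#' Segment a session log into collection cycles
#'
#' One cycle per collection event. A cycle starts where the previous one
#' ended (the first at the session start), so start positions are the
#' positions at the previous event's end tick; the target layout at cycle
#' start and the outcomes of the two preceding cycles are attached.
#'
#' @param session A `ccf_session`.
#' @return A data frame of class `ccf_cycles`, one row per cycle, with
#'   timing (`t_start_s`, `t_collect_start_s`, `t_end_s`), start positions
#'   (`ax_cm` .. `by_cm`), the cycle-start layout (`single_x_cm` ..
#'   `jointB_y_cm`), `target_kind`, `collector`, payoffs, and
#'   `prev1_kind`/`prev2_kind` (`NA` for the first two cycles). The 120 Hz
#'   position matrix and tick indices are attached as attributes so
#'   trajectory-level operations ([classify_session()], [cycle_kinematics()])
#'   can slice each cycle's movement; `config` is attached as an attribute.
#' @export
segment_cycles <- function(session) {
  stopifnot(inherits(session, "ccf_session"))
  ev <- session$events
  cfg <- session$config
  if (nrow(ev) == 0L) {
    out <- data.frame()
    class(out) <- c("ccf_cycles", "data.frame")
    return(out)
  }
  if (is.unsorted(ev$t_end_s, strictly = TRUE))
    stop("events are not strictly increasing in time", call. = FALSE)

  n <- nrow(ev)
  t_start <- c(0, ev$t_end_s[-n])
  dt <- cfg$dt
  tick_start <- as.integer(round(t_start / dt))
  tick_collect <- as.integer(round(ev$t_collect_start_s / dt))
  tick_end <- as.integer(round(ev$t_end_s / dt))

  pos <- as.matrix(session$positions[, c("ax_cm", "ay_cm", "bx_cm", "by_cm")])
  srow <- tick_start + 1L
  if (max(tick_end) + 1L > nrow(pos))
    stop("positions do not cover the event time span", call. = FALSE)

  out <- data.frame(
    cycle = seq_len(n),
    t_start_s = t_start,
    t_collect_start_s = ev$t_collect_start_s,
    t_end_s = ev$t_end_s,
    ax_cm = pos[srow, 1L], ay_cm = pos[srow, 2L],
    bx_cm = pos[srow, 3L], by_cm = pos[srow, 4L],
    single_x_cm = ev$single_x_cm, single_y_cm = ev$single_y_cm,
    jointA_x_cm = ev$jointA_x_cm, jointA_y_cm = ev$jointA_y_cm,
    jointB_x_cm = ev$jointB_x_cm, jointB_y_cm = ev$jointB_y_cm,
    target_x_cm = ev$target_x_cm, target_y_cm = ev$target_y_cm,
    target_kind = ev$target_kind,
    collector = ev$collector,
    payoff_a_cents = ev$payoff_a_cents,
    payoff_b_cents = ev$payoff_b_cents,
    prev1_kind = c(NA, ev$target_kind[-n]),
    prev2_kind = c(NA, NA, if (n > 2L) ev$target_kind[seq_len(n - 2L)]),
    stringsAsFactors = FALSE
  )
  out$tick_start <- tick_start
  out$tick_collect <- tick_collect
  out$tick_end <- tick_end
  attr(out, "positions") <- pos
  attr(out, "config") <- cfg
  class(out) <- c("ccf_cycles", "data.frame")
  out
}

# Position slice of one agent over a tick range (inclusive, 0-based ticks).
trajectory_slice <- function(cycles, i, agent = c("A", "B"),
                             phase = c("acquisition", "cycle")) {
  agent <- match.arg(agent)
  phase <- match.arg(phase)
  pos <- attr(cycles, "positions")
  cols <- if (agent == "A") 1:2 else 3:4
  t1 <- if (phase == "acquisition") cycles$tick_collect[i] else cycles$tick_end[i]
  pos[(cycles$tick_start[i]:t1) + 1L, cols, drop = FALSE]
}

#' Moving-average FST time course
#'
#' The fraction of single targets among all collections inside a trailing
#' window, evaluated at event times (FST is event-driven; evaluating at
#' ticks would only add flat segments).
#'
#' @param cycles A `ccf_cycles` frame (or any data frame with `t_end_s` and
#'   `target_kind`).
#' @param window Window length (s); the study uses 60 s (and 30 s for
#'   model-prediction time courses).
#' @return Data frame with `t_s` (event time), `fst`, and `n_events` (events
#'   inside the window).
#' @export
fst_timecourse <- function(cycles, window = 60) {
  stopifnot(window > 0)
  t <- cycles$t_end_s
  is_single <- as.numeric(cycles$target_kind == "single")
  cs <- cumsum(is_single)
  # index of the last event at or before t - window
  lo <- findInterval(t - window, t)
  n_ev <- seq_along(t) - lo
  n_single <- cs - c(0, cs)[lo + 1L]
  data.frame(t_s = t, fst = n_single / n_ev, n_events = n_ev)
}

#' Stable strategy, convergence time and group label
#'
#' The stable FST `phi` is the event-weighted fraction of single targets
#' from `analysis_start` (default: the first 10 minutes are excluded) to the
#' session end. The convergence time is the earliest time after which the
#' moving-average FST stays within `delta` of `phi` for the rest of the
#' session. Dyads are grouped as cooperative (`phi <= 0.1`), competitive
#' (`phi >= 0.9`) or intermediate. A block-inconsistency flag is raised when
#' per-block `phi` values differ by more than `delta`.
#'
#' @param cycles A `ccf_cycles` frame.
#' @param analysis_start Start of the stable analysis window (s).
#' @param delta Stability tolerance on the FST scale.
#' @param window Moving-average window (s) for the convergence criterion.
#' @param block_duration Block length (s) for the consistency check.
#' @return A list with `phi`, `group`, `convergence_s`, `block_inconsistent`,
#'   `phi_blocks`, `payoff_a_cents`, `payoff_b_cents`, and `n_events`.
#' @export
stable_strategy <- function(cycles, analysis_start = 600, delta = 0.1,
                            window = 60, block_duration = 1200) {
  t <- cycles$t_end_s
  if (length(t) == 0L || max(t) < analysis_start)
    stop("session shorter than `analysis_start`", call. = FALSE)
  stable <- cycles$t_end_s >= analysis_start
  phi <- mean(cycles$target_kind[stable] == "single")

  tc <- fst_timecourse(cycles, window)
  bad <- which(abs(tc$fst - phi) > delta)
  convergence_s <- if (length(bad) == 0L) 0 else tc$t_s[max(bad)]

  block <- floor(t / block_duration)
  phi_blocks <- tapply(cycles$target_kind == "single", block, mean)
  block_inconsistent <- length(phi_blocks) > 1L &&
    (max(phi_blocks) - min(phi_blocks)) > delta

  group <- if (phi <= 0.1) "cooperative"
           else if (phi >= 0.9) "competitive"
           else "intermediate"

  list(phi = phi, group = group, convergence_s = convergence_s,
       block_inconsistent = block_inconsistent,
       phi_blocks = as.numeric(phi_blocks),
       payoff_a_cents = sum(cycles$payoff_a_cents),
       payoff_b_cents = sum(cycles$payoff_b_cents),
       n_events = nrow(cycles))
}
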