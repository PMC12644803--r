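#' Game configuration
#'
#' Builds the configuration of the cooperation-competition foraging game: a
#' square field on which two agents collect one winner-takes-all "single"
#' target and two asymmetric "joint" targets. Defaults reproduce the study
#' conditions: a 51 cm field sampled at 120 Hz, 5 cm targets, a 42.6 cm/s
#' speed cap, a 1 s hover to collect, and payoffs of 7 cents for a single
#' target versus 5 + 2 cents for a joint target, so that both target types
#' carry the same joint payoff.
#'
#' @param field_side Side of the square field (cm).
#' @param target_diameter Target diameter (cm).
#' @param agent_diameter Agent (cursor) diameter (cm).
#' @param hover_time Time an agent must remain on a target to collect it (s).
#' @param max_speed Maximum agent speed (cm/s); commanded velocities above
#'   this are clipped.
#' @param tick_rate Position sampling rate (Hz). `tick_rate * hover_time`
#'   must be an integer number of ticks.
#' @param payoff_single Payoff of a single target (cents), all to the winner.
#' @param payoff_joint_major,payoff_joint_minor Payoffs of a joint target
#'   (cents) to the favoured and non-favoured agent; their sum must equal
#'   `payoff_single`.
#' @param session_duration Duration of one session block (s).
#' @return An object of class `ccf_config` (a named list).
#' @examples
#' cfg <- game_config()
#' cfg$max_speed
#' @export
game_config <- function(field_side = 51,
                        target_diameter = 5,
                        agent_diameter = 2,
                        hover_time = 1.0,
                        max_speed = 42.6,
                        tick_rate = 120,
                        payoff_single = 7,
                        payoff_joint_major = 5,
                        payoff_joint_minor = 2,
                        session_duration = 1200) {
  cfg <- list(
    field_side = field_side,
    target_diameter = target_diameter,
    agent_diameter = agent_diameter,
    hover_time = hover_time,
    max_speed = max_speed,
    tick_rate = tick_rate,
    payoff_single = payoff_single,
    payoff_joint_major = payoff_joint_major,
    payoff_joint_minor = payoff_joint_minor,
    session_duration = session_duration
  )
  lengths_pos <- c("field_side", "target_diameter", "agent_diameter",
                   "hover_time", "max_speed", "tick_rate", "session_duration")
  for (nm in lengths_pos) {
    v <- cfg[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      stop("`", nm, "` must be a single positive finite number", call. = FALSE)
  }
  if (payoff_joint_major + payoff_joint_minor != payoff_single)
    stop("joint payoffs must sum to the single-target payoff ",
         "(equal joint payoff for both target types)", call. = FALSE)
  hover_ticks <- tick_rate * hover_time
  if (abs(hover_ticks - round(hover_ticks)) > 1e-9)
    stop("`tick_rate * hover_time` must be an integer number of ticks",
         call. = FALSE)
  # The spawn region is inset by the target radius; three non-overlapping
  # targets must fit.
  if (field_side - target_diameter <= 2 * target_diameter)
    stop("field too small to host three non-overlapping targets", call. = FALSE)
  cfg$hover_ticks <- as.integer(round(hover_ticks))
  cfg$dt <- 1 / tick_rate
  cfg$target_radius <- target_diameter / 2
  structure(cfg, class = "ccf_config")
}

#' @export
print.ccf_config <- function(x, ...) {
  cat("<ccf_config> ", x$field_side, " cm field, ", x$tick_rate, " Hz, ",
      x$max_speed, " cm/s cap, hover ", x$hover_time, " s, payoffs ",
      x$payoff_single, " / ", x$payoff_joint_major, "+",
      x$payoff_joint_minor, " cents\n", sep = "")
  invisible(x)
}

# Uniform target position in the admissible (radius-inset) region.
sample_target_position <- function(cfg) {
  r <- cfg$target_radius
  runif(2, min = r, max = cfg$field_side - r)
}

# Rejection-sample a target position that does not overlap `others`
# (matrix of centres); overlap means centre distance <= target_diameter.
sample_nonoverlapping <- function(cfg, others) {
  repeat {
    p <- sample_target_position(cfg)
    if (is.null(others) || nrow(others) == 0L ||
        all(dist_to(p, others) > cfg$target_diameter))
      return(p)
  }
}
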