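# Heuristic trajectory classification: each collection cycle is assigned the
# first matching class of invitation, failed invitation, strongly curved,
# different targets, one ahead, concurrent -- in that order. The numeric
# cutoffs are conventions of this implementation; all are configurable for
# sensitivity analysis.

TRAJ_CLASSES <- c("invitation", "failed_invitation", "strongly_curved",
                  "different_targets", "one_ahead", "concurrent")

#' Classification thresholds
#'
#' @param c_thr Curvature-ratio threshold (path length / chord) above which
#'   a trajectory counts as strongly curved.
#' @param t_lead Movement-onset lag (s) separating "one ahead" from
#'   "concurrent".
#' @param t_dwell Minimum dwell (s) on a joint target before cycle start to
#'   count as an invitation.
#' @param capture_r Radius (cm) for "on/heading to a target"; defaults to
#'   the target radius.
#' @param onset_frac Fraction of the speed cap that the speed toward the
#'   collected target must exceed (for 3 consecutive ticks) to mark
#'   movement onset.
#' @param min_chord Minimum chord (cm) below which the curvature ratio is
#'   taken as 1 (the agent essentially did not move).
#' @return A named list of thresholds.
#' @export
classify_params <- function(c_thr = 1.25, t_lead = 0.25, t_dwell = 0.5,
                            capture_r = NULL, onset_frac = 0.1,
                            min_chord = 1) {
  list(c_thr = c_thr, t_lead = t_lead, t_dwell = t_dwell,
       capture_r = capture_r, onset_frac = onset_frac, min_chord = min_chord)
}

path_length <- function(xy) {
  if (nrow(xy) < 2L) return(0)
  sum(sqrt(diff(xy[, 1L])^2 + diff(xy[, 2L])^2))
}

curvature_ratio <- function(xy, min_chord) {
  chord <- dist2(xy[1L, ], xy[nrow(xy), ])
  if (chord < min_chord) return(1)
  max(1, path_length(xy) / chord)
}

# First tick index (0-based, relative to cycle start) at which the speed
# toward `target` exceeds `v_thr` for >= 3 consecutive ticks; NA if never.
movement_onset <- function(xy, target, v_thr, dt) {
  if (nrow(xy) < 4L) return(NA_integer_)
  d <- dist_to(target, xy)
  appr <- -diff(d) / dt  # speed toward the target
  run <- appr > v_thr
  r <- rle(run)
  ends <- cumsum(r$lengths)
  ok <- which(r$values & r$lengths >= 3L)
  if (length(ok) == 0L) return(NA_integer_)
  ends[ok[1L]] - r$lengths[ok[1L]]
}

#' Classify every cycle of a session
#'
#' Applies the ordered heuristic rules to each collection cycle:
#' (1) *invitation*: an agent has been dwelling on a joint target since at
#' least `t_dwell` before cycle start, and that target is collected
#' (sub-label *passive* when the dwell spans the whole previous collection
#' period, *active* otherwise); (2) *failed invitation*: such a dwell is
#' present but a different target is collected; (3) *strongly curved*:
#' either agent's path-to-chord ratio during acquisition exceeds `c_thr`;
#' (4) *different targets*: at collection start the two agents are at
#' different targets; (5) *one ahead*: both to the same target with
#' movement-onset lag above `t_lead`; (6) *concurrent* otherwise.
#'
#' @param cycles A `ccf_cycles` frame from [segment_cycles()].
#' @param params Thresholds from [classify_params()].
#' @return Data frame with one row per cycle: `cycle`, `label`, `sublabel`,
#'   `curvature_a`, `curvature_b`, `lead_lag_s` (positive when agent A's
#'   onset precedes B's).
#' @export
classify_session <- function(cycles, params = classify_params()) {
  cfg <- attr(cycles, "config")
  capture_r <- params$capture_r
  if (is.null(capture_r)) capture_r <- cfg$target_radius
  dt <- cfg$dt
  dwell_ticks <- as.integer(round(params$t_dwell / dt))
  v_thr <- params$onset_frac * cfg$max_speed
  pos <- attr(cycles, "positions")
  n <- nrow(cycles)

  label <- sublabel <- character(n)
  curv_a <- curv_b <- lead_lag <- rep(NA_real_, n)

  for (i in seq_len(n)) {
    ts <- cycles$tick_start[i]; tc <- cycles$tick_collect[i]
    if (tc - ts < 2L) { label[i] <- "unclassifiable"; sublabel[i] <- ""; next }
    xa <- pos[(ts:tc) + 1L, 1:2, drop = FALSE]
    xb <- pos[(ts:tc) + 1L, 3:4, drop = FALSE]
    joints <- rbind(
      jointA = c(cycles$jointA_x_cm[i], cycles$jointA_y_cm[i]),
      jointB = c(cycles$jointB_x_cm[i], cycles$jointB_y_cm[i])
    )
    outcome <- cycles$target_kind[i]
    target <- c(cycles$target_x_cm[i], cycles$target_y_cm[i])

    curv_a[i] <- curvature_ratio(xa, params$min_chord)
    curv_b[i] <- curvature_ratio(xb, params$min_chord)

    # (1)/(2) invitation dwell: an agent continuously on a joint target over
    # [t_start - t_dwell, t_start]
    dwell_agent <- NA_character_; dwell_joint <- NA_character_
    if (ts >= dwell_ticks) {
      back <- ((ts - dwell_ticks):ts) + 1L
      for (ag in c("A", "B")) {
        cols <- if (ag == "A") 1:2 else 3:4
        for (j in rownames(joints)) {
          dj <- dist_to(joints[j, ], pos[back, cols, drop = FALSE])
          if (all(dj <= capture_r)) { dwell_agent <- ag; dwell_joint <- j }
        }
      }
    }
    if (!is.na(dwell_agent)) {
      if (outcome == dwell_joint) {
        label[i] <- "invitation"
        # passive: the dwell spans the whole previous collection period
        passive <- FALSE
        if (i > 1L) {
          pc <- cycles$tick_collect[i - 1L]
          cols <- if (dwell_agent == "A") 1:2 else 3:4
          span <- (pc:ts) + 1L
          passive <- all(dist_to(joints[dwell_joint, ],
                                 pos[span, cols, drop = FALSE]) <= capture_r)
        }
        sublabel[i] <- if (passive) "passive" else "active"
      } else {
        label[i] <- "failed_invitation"
        sublabel[i] <- dwell_joint
      }
      next
    }

    # (3) strongly curved
    if (max(curv_a[i], curv_b[i]) > params$c_thr) {
      label[i] <- "strongly_curved"
      sublabel[i] <- if (curv_a[i] >= curv_b[i]) "A" else "B"
      next
    }

    # (4) different targets: terminal target of each agent at collection start
    all_targets <- rbind(single = c(cycles$single_x_cm[i], cycles$single_y_cm[i]),
                         joints)
    term <- function(p) {
      d <- dist_to(p, all_targets)
      if (min(d) <= capture_r) rownames(all_targets)[which.min(d)] else NA_character_
    }
    ta <- term(xa[nrow(xa), ]); tb <- term(xb[nrow(xb), ])
    if (!is.na(ta) && !is.na(tb) && ta != tb) {
      label[i] <- "different_targets"
      sublabel[i] <- paste(ta, tb, sep = "/")
      next
    }

    # (5)/(6) both to the collected target: onset lag
    oa <- movement_onset(xa, target, v_thr, dt)
    ob <- movement_onset(xb, target, v_thr, dt)
    # an agent with no onset (already on target, or never moving) is treated
    # as onsetting only at collection start; such cycles are tagged "_solo"
    # so that contested-race analyses can exclude them
    solo <- xor(is.na(oa), is.na(ob))
    if (is.na(oa)) oa <- tc - ts
    if (is.na(ob)) ob <- tc - ts
    lead_lag[i] <- (ob - oa) * dt
    kind_tag <- if (outcome == "single") "single" else "joint"
    if (solo) kind_tag <- paste0(kind_tag, "_solo")
    if (abs(lead_lag[i]) > params$t_lead) {
      label[i] <- "one_ahead"
      sublabel[i] <- kind_tag
    } else {
      label[i] <- "concurrent"
      sublabel[i] <- kind_tag
    }
  }

  data.frame(cycle = cycles$cycle, label = label, sublabel = sublabel,
             curvature_a = curv_a, curvature_b = curv_b,
             lead_lag_s = lead_lag, stringsAsFactors = FALSE)
}

#' Markov transition matrix of trajectory classes
#'
#' Maximum-likelihood transition probabilities between consecutive cycles'
#' classes. Rows with no observations are left `NaN` and flagged.
#'
#' @param labels Character vector of class labels (in session order);
#'   unclassifiable cycles break the chain at that point.
#' @return A list of class `ccf_transitions` with `prob` (6 x 6
#'   row-stochastic matrix), `counts`, and `undefined_rows`.
#' @export
transition_chain <- function(labels) {
  if (length(labels) < 2L) stop("need at least 2 labelled cycles", call. = FALSE)
  f <- factor(labels, levels = TRAJ_CLASSES)
  from <- f[-length(f)]; to <- f[-1L]
  ok <- !is.na(from) & !is.na(to)
  counts <- table(from = from[ok], to = to[ok])
  counts <- unclass(counts)
  rs <- rowSums(counts)
  prob <- counts / ifelse(rs == 0, NA, rs)
  structure(list(prob = prob, counts = counts, undefined_rows = rs == 0),
            class = "ccf_transitions")
}

#' Class composition across choice-uncertainty bins
#'
#' Fractions of trajectory classes within bins of the model's prediction
#' entropy. Dyad-level filtering (the study drops FST >= 0.9 dyads, whose
#' choice is always near-certain) is the caller's responsibility.
#'
#' @param labels Class labels aligned with `entropies`.
#' @param entropies Prediction entropy (bits) per cycle.
#' @param breaks Bin breaks on the entropy axis (default: 4 equal bins over
#'   `[0, log2 3]`).
#' @return Data frame: one row per (bin, class) with `fraction` and the bin
#'   occupancy `n`.
#' @export
entropy_by_class <- function(labels, entropies,
                             breaks = seq(0, log2(3), length.out = 5L)) {
  stopifnot(length(labels) == length(entropies))
  keep <- labels %in% TRAJ_CLASSES
  labels <- factor(labels[keep], levels = TRAJ_CLASSES)
  bin <- cut(entropies[keep], breaks = breaks, include.lowest = TRUE)
  tab <- table(bin, labels)
  n_bin <- rowSums(tab)
  frac <- tab / ifelse(n_bin == 0, NA, n_bin)
  out <- as.data.frame(frac, stringsAsFactors = FALSE)
  names(out) <- c("bin", "label", "fraction")
  out$n <- as.integer(tab[cbind(out$bin, out$label)])
  out
}

#' Entropy reduction attributable to invitations
#'
#' Pairs, per cycle, the full model's prediction entropy with the entropy
#' after zeroing the invitation features (the counterfactual "no invite
#' seen" prediction), and tests the reduction on invitation-bearing cycles
#' with a Wilcoxon signed-rank test; the effect size is the rank-biserial
#' correlation.
#'
#' @param fit A full-model `ccf_choice_fit`.
#' @param design The `ccf_design` the fit was computed on.
#' @return List with `n`, `median_with`, `median_without`, `statistic`,
#'   `p_value`, `rank_biserial`.
#' @export
invitation_entropy_test <- function(fit, design) {
  stopifnot(inherits(fit, "ccf_choice_fit"), fit$model == "full")
  za0 <- design$za; zb0 <- design$zb
  za0[, c("invite_own", "invite_other")] <- 0
  zb0[, c("invite_own", "invite_other")] <- 0
  h_with <- fit$entropy_bits
  h_without <- prediction_entropy(softmax_probs(fit$theta, za0, zb0))
  idx <- which(design$invite != "none")
  if (length(idx) < 3L)
    stop("too few invitation cycles for a paired test", call. = FALSE)
  d <- h_with[idx] - h_without[idx]
  wt <- stats::wilcox.test(h_with[idx], h_without[idx], paired = TRUE,
                           exact = FALSE)
  nz <- d[d != 0]
  rk <- rank(abs(nz))
  w_pos <- sum(rk[nz > 0]); w_neg <- sum(rk[nz < 0])
  rb <- if (w_pos + w_neg == 0) 0 else (w_pos - w_neg) / (w_pos + w_neg)
  list(n = length(idx),
       median_with = stats::median(h_with[idx]),
       median_without = stats::median(h_without[idx]),
       statistic = unname(wt$statistic), p_value = wt$p.value,
       rank_biserial = rb)
}
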