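# Dyadic target-choice models: relevant distances, the weighted
# path-minimization predictor and its weight fit, the multinomial softmax
# model with across-cycle predictors (previous outcomes, invitations),
# cross-validated accuracy, AIC, prediction entropy, and Wald /
# Benjamini-Hochberg inference.

#' Relevant distances for each cycle
#'
#' @param cycles A `ccf_cycles` frame (start positions and layout columns).
#' @return Data frame with `d_single` (minimum over agents), `d_jointA` and
#'   `d_jointB` (maximum over agents), in cm.
#' @export
relevant_distances <- function(cycles) {
  da <- function(tx, ty) sqrt((cycles$ax_cm - tx)^2 + (cycles$ay_cm - ty)^2)
  db <- function(tx, ty) sqrt((cycles$bx_cm - tx)^2 + (cycles$by_cm - ty)^2)
  data.frame(
    d_single = pmin(da(cycles$single_x_cm, cycles$single_y_cm),
                    db(cycles$single_x_cm, cycles$single_y_cm)),
    d_jointA = pmax(da(cycles$jointA_x_cm, cycles$jointA_y_cm),
                    db(cycles$jointA_x_cm, cycles$jointA_y_cm)),
    d_jointB = pmax(da(cycles$jointB_x_cm, cycles$jointB_y_cm),
                    db(cycles$jointB_x_cm, cycles$jointB_y_cm))
  )
}

#' Weighted path-minimization prediction
#'
#' Predicts the target with the minimal preference-weighted relevant
#' distance: the single target's distance is weighted by `1 - w`, each joint
#' target's by `w`. Ties go to the smaller unweighted distance, then to the
#' fixed kind order single < jointA < jointB. `w = 0.5` is the plain
#' closest-target rule.
#'
#' @param d Data frame from [relevant_distances()] (or a length-3 vector).
#' @param w Weight in `[0, 1]`.
#' @return Character vector of predicted target kinds.
#' @export
predict_weighted <- function(d, w) {
  stopifnot(w >= 0, w <= 1)
  if (is.null(dim(d))) d <- as.data.frame(as.list(stats::setNames(
    as.numeric(d), c("d_single", "d_jointA", "d_jointB"))))
  dm <- cbind(d$d_single, d$d_jointA, d$d_jointB)
  wd <- cbind(dm[, 1L] * (1 - w), dm[, 2L] * w, dm[, 3L] * w)
  # argmin with deterministic tie-breaks
  pred <- integer(nrow(dm))
  for (i in seq_len(nrow(dm)))
    pred[i] <- weighted_argmin(dm[i, ], w)
  TARGET_KINDS[pred]
}

#' Fit the preference weight from observed choices
#'
#' Finds the weight `w` at which the fraction of cycles whose weighted
#' path-minimization prediction is the single target matches the dyad's
#' observed fraction of single targets (FST). The predicted FST is a
#' non-decreasing step function of `w`, so a monotone bisection converges to
#' within `1 / n` cycles; an unreachable FST returns the boundary weight.
#'
#' @param cycles A `ccf_cycles` frame (at least 20 cycles).
#' @return The fitted weight, with attributes `predicted_fst` and
#'   `observed_fst`.
#' @export
fit_weight <- function(cycles) {
  n <- nrow(cycles)
  if (n < 20L) stop("need at least 20 cycles to fit the weight", call. = FALSE)
  d <- relevant_distances(cycles)
  obs <- mean(cycles$target_kind == "single")
  pf <- function(w) mean(predict_weighted(d, w) == "single")
  tol <- 1 / n
  lo <- 0; hi <- 1
  f_lo <- pf(lo); f_hi <- pf(hi)
  w <- if (f_hi <= obs) 1 else if (f_lo >= obs) 0 else {
    for (i in 1:40) {
      mid <- (lo + hi) / 2
      fm <- pf(mid)
      if (abs(fm - obs) <= tol * 0.5) break
      if (fm < obs) lo <- mid else hi <- mid
    }
    mid
  }
  structure(w, predicted_fst = pf(w), observed_fst = obs)
}

# -- design construction -----------------------------------------------------

#' Build the choice-model design
#'
#' Encodes each cycle (the first two are dropped: they lack the two-cycle
#' history) as the features of the softmax choice model: the three relevant
#' distances (standardized within the dyad; the two joint distances share
#' pooled statistics so standardization preserves the agent/joint-label
#' symmetry), indicators of the kinds collected in the two previous cycles,
#' and the invitation indicator -- set when at cycle start one agent is
#' within `invite_radius` of a joint target while the other agent is not on
#' that target.
#'
#' The A/B interchangeability of the problem is built into the model by
#' parameter tying: each free coefficient multiplies a feature in "own"
#' coordinates for class jointA and in mirrored coordinates for class
#' jointB, which is equivalent to augmenting the data with mirrored rows
#' sharing one coefficient vector.
#'
#' @param cycles A `ccf_cycles` frame with `prev1_kind`/`prev2_kind`.
#' @param invite_radius Radius (cm) defining "near a joint target"; defaults
#'   to the target radius.
#' @return A list of class `ccf_design`: `za`, `zb` (n x 10 feature matrices
#'   for the jointA and jointB class scores), `y` (observed kinds), `invite`
#'   (kind of the invited joint target, or `"none"`), `kept` (row indices of
#'   `cycles` retained), and `scaling`.
#' @export
build_design <- function(cycles, invite_radius = NULL) {
  cfg <- attr(cycles, "config")
  if (is.null(invite_radius))
    invite_radius <- if (!is.null(cfg)) cfg$target_radius else 2.5
  keep <- which(!is.na(cycles$prev1_kind) & !is.na(cycles$prev2_kind))
  cy <- cycles[keep, ]
  d <- relevant_distances(cy)

  # standardize: single on its own, joints pooled (symmetry-preserving)
  mu_s <- mean(d$d_single); sd_s <- stats::sd(d$d_single)
  dj <- c(d$d_jointA, d$d_jointB)
  mu_j <- mean(dj); sd_j <- stats::sd(dj)
  if (!is.finite(sd_s) || sd_s < 1e-9) sd_s <- 1
  if (!is.finite(sd_j) || sd_j < 1e-9) sd_j <- 1
  zs <- (d$d_single - mu_s) / sd_s
  zja <- (d$d_jointA - mu_j) / sd_j
  zjb <- (d$d_jointB - mu_j) / sd_j

  # invitation: one agent near a joint target, the other not on it
  inv <- rep("none", nrow(cy))
  for (j in c("jointA", "jointB")) {
    tx <- cy[[paste0(j, "_x_cm")]]; ty <- cy[[paste0(j, "_y_cm")]]
    da <- sqrt((cy$ax_cm - tx)^2 + (cy$ay_cm - ty)^2)
    db <- sqrt((cy$bx_cm - tx)^2 + (cy$by_cm - ty)^2)
    hit <- (da <= invite_radius & db > invite_radius) |
           (db <= invite_radius & da > invite_radius)
    inv[hit] <- j  # with both joints flagged (rare), the later one wins
  }

  p1 <- cy$prev1_kind; p2 <- cy$prev2_kind
  za <- cbind(
    intercept = 1,
    d_single = zs,
    d_joint_own = zja,
    d_joint_other = zjb,
    prev1_joint_own = as.numeric(p1 == "jointA"),
    prev1_joint_other = as.numeric(p1 == "jointB"),
    prev2_joint_own = as.numeric(p2 == "jointA"),
    prev2_joint_other = as.numeric(p2 == "jointB"),
    invite_own = as.numeric(inv == "jointA"),
    invite_other = as.numeric(inv == "jointB")
  )
  zb <- za
  swap <- c(1L, 2L, 4L, 3L, 6L, 5L, 8L, 7L, 10L, 9L)
  zb <- za[, swap, drop = FALSE]
  colnames(zb) <- colnames(za)

  structure(list(za = za, zb = zb, y = cy$target_kind, invite = inv,
                 kept = keep,
                 scaling = c(mu_single = mu_s, sd_single = sd_s,
                             mu_joint = mu_j, sd_joint = sd_j),
                 invite_radius = invite_radius),
            class = "ccf_design")
}

#' Mirror a cycles frame (swap agents A/B together with jointA/jointB)
#'
#' The game is symmetric under relabelling the agents together with the
#' joint targets; the mirrored log is an equally valid session. Used to test
#' the swap-equivariance of designs and fits.
#'
#' @param cycles A `ccf_cycles` frame.
#' @return The mirrored `ccf_cycles` frame.
#' @export
mirror_cycles <- function(cycles) {
  m <- cycles
  m$ax_cm <- cycles$bx_cm; m$ay_cm <- cycles$by_cm
  m$bx_cm <- cycles$ax_cm; m$by_cm <- cycles$ay_cm
  m$jointA_x_cm <- cycles$jointB_x_cm; m$jointA_y_cm <- cycles$jointB_y_cm
  m$jointB_x_cm <- cycles$jointA_x_cm; m$jointB_y_cm <- cycles$jointA_y_cm
  swap_kind <- function(k) ifelse(k == "jointA", "jointB",
                           ifelse(k == "jointB", "jointA", k))
  m$target_kind <- swap_kind(cycles$target_kind)
  m$prev1_kind <- swap_kind(cycles$prev1_kind)
  m$prev2_kind <- swap_kind(cycles$prev2_kind)
  if ("collector" %in% names(m))
    m$collector <- ifelse(cycles$collector == "A", "B",
                    ifelse(cycles$collector == "B", "A", cycles$collector))
  if ("payoff_a_cents" %in% names(m)) {
    m$payoff_a_cents <- cycles$payoff_b_cents
    m$payoff_b_cents <- cycles$payoff_a_cents
  }
  pos <- attr(cycles, "positions")
  if (!is.null(pos)) attr(m, "positions") <- pos[, c(3L, 4L, 1L, 2L), drop = FALSE]
  m
}

# -- softmax likelihood ------------------------------------------------------

softmax_probs <- function(theta, za, zb) {
  ua <- drop(za %*% theta)
  ub <- drop(zb %*% theta)
  mx <- pmax(0, ua, ub)
  ea <- exp(ua - mx); eb <- exp(ub - mx); es <- exp(-mx)
  z <- es + ea + eb
  cbind(single = es / z, jointA = ea / z, jointB = eb / z)
}

neg_loglik <- function(theta, za, zb, ycode, ridge = 0) {
  p <- softmax_probs(theta, za, zb)
  ll <- sum(log(pmax(p[cbind(seq_along(ycode), ycode)], 1e-300)))
  -ll + ridge * sum(theta^2)
}

neg_gradient <- function(theta, za, zb, ycode, ridge = 0) {
  p <- softmax_probs(theta, za, zb)
  ra <- (ycode == 2L) - p[, 2L]
  rb <- (ycode == 3L) - p[, 3L]
  -(drop(crossprod(za, ra)) + drop(crossprod(zb, rb))) + 2 * ridge * theta
}

neg_hessian <- function(theta, za, zb, ycode, ridge = 0) {
  p <- softmax_probs(theta, za, zb)
  wa <- p[, 2L] * (1 - p[, 2L])
  wb <- p[, 3L] * (1 - p[, 3L])
  wab <- -p[, 2L] * p[, 3L]
  h <- crossprod(za * wa, za) + crossprod(zb * wb, zb) +
    crossprod(za * wab, zb) + crossprod(zb * wab, za)
  h + diag(2 * ridge, length(theta))
}

# -- model fitting -----------------------------------------------------------

fit_theta <- function(za, zb, ycode, ridge = 0, grad_tol = 1e-6) {
  k <- ncol(za)
  opt <- stats::optim(rep(0, k), fn = neg_loglik, gr = neg_gradient,
                      za = za, zb = zb, ycode = ycode, ridge = ridge,
                      method = "BFGS",
                      control = list(maxit = 1000, reltol = 1e-12))
  theta <- opt$par
  g <- neg_gradient(theta, za, zb, ycode, ridge)
  list(theta = theta, value = opt$value, grad_norm = max(abs(g)),
       converged = max(abs(g)) < grad_tol && opt$convergence == 0)
}

#' Fit the multinomial softmax choice model
#'
#' Maximizes the multinomial log-likelihood of the observed target choices
#' under `P(j | x) = softmax(theta . z_j)` by BFGS from a zero start, with
#' the A/B symmetry tied into the parametrization (see [build_design()]).
#' Cross-validation uses contiguous blocks of cycles (respecting the serial
#' dependence of a session); the reported accuracy is the mean over folds of
#' the held-out fraction whose highest-probability class matches the
#' outcome. If the optimum is suspect (non-convergence or runaway
#' coefficients, e.g. under complete separation), the fit is repeated with a
#' small L2 ridge (1e-4) and a warning.
#'
#' @param design A `ccf_design` from [build_design()].
#' @param k_folds Number of contiguous cross-validation folds (>= 2).
#' @param model `"full"` (distances + history + invitations, 10 free
#'   parameters) or `"distance"` (distances only, 4).
#' @return An object of class `ccf_choice_fit`: `theta` (named), `loglik`,
#'   `k`, `aic`, `cv_accuracy`, `prob` (n x 3 matrix), `entropy_bits`,
#'   `predicted`, `observed`, `se`, `z`, `wald_p`, `hessian`, plus
#'   convergence flags.
#' @export
fit_glm <- function(design, k_folds = 5, model = c("full", "distance")) {
  stopifnot(inherits(design, "ccf_design"), k_folds >= 2)
  model <- match.arg(model)
  cols <- if (model == "distance") 1:4 else seq_len(ncol(design$za))
  za <- design$za[, cols, drop = FALSE]
  zb <- design$zb[, cols, drop = FALSE]
  ycode <- kind_index(design$y)
  n <- length(ycode)
  if (n < 10L * k_folds)
    stop("too few cycles for ", k_folds, "-fold cross-validation", call. = FALSE)

  fit <- fit_theta(za, zb, ycode)
  ridged <- FALSE
  if (!fit$converged || max(abs(fit$theta)) > 50) {
    warning("suspect optimum (possible separation); refitting with L2 ridge 1e-4")
    fit <- fit_theta(za, zb, ycode, ridge = 1e-4)
    ridged <- TRUE
  }
  theta <- stats::setNames(fit$theta, colnames(za))
  loglik <- -neg_loglik(fit$theta, za, zb, ycode)
  k <- length(theta)
  aic <- 2 * k - 2 * loglik

  prob <- softmax_probs(fit$theta, za, zb)
  predicted <- TARGET_KINDS[max.col(prob, ties.method = "first")]

  # contiguous-block cross-validation
  fold <- cut(seq_len(n), breaks = k_folds, labels = FALSE)
  acc <- numeric(k_folds)
  for (f in seq_len(k_folds)) {
    te <- fold == f
    ft <- fit_theta(za[!te, , drop = FALSE], zb[!te, , drop = FALSE],
                    ycode[!te], ridge = if (ridged) 1e-4 else 0)
    ph <- softmax_probs(ft$theta, za[te, , drop = FALSE],
                        zb[te, , drop = FALSE])
    acc[f] <- mean(max.col(ph, ties.method = "first") == ycode[te])
  }

  h <- neg_hessian(fit$theta, za, zb, ycode, ridge = if (ridged) 1e-4 else 0)
  vcov_ok <- TRUE
  se <- rep(NA_real_, k)
  vc <- tryCatch(solve(h), error = function(e) NULL)
  if (is.null(vc) || any(!is.finite(diag(vc))) || any(diag(vc) <= 0)) {
    vcov_ok <- FALSE
  } else {
    se <- sqrt(diag(vc))
  }
  z <- theta / se
  wald_p <- 2 * stats::pnorm(-abs(z))

  structure(list(
    model = model, theta = theta, loglik = loglik, k = k, aic = aic,
    cv_accuracy = mean(acc), cv_fold_accuracy = acc,
    prob = prob, entropy_bits = prediction_entropy(prob),
    predicted = predicted, observed = design$y,
    se = se, z = z, wald_p = wald_p, hessian = h, vcov_ok = vcov_ok,
    converged = fit$converged, ridged = ridged, n = n
  ), class = "ccf_choice_fit")
}

#' @export
print.ccf_choice_fit <- function(x, ...) {
  cat("<ccf_choice_fit> ", x$model, " model, n = ", x$n,
      ", loglik = ", round(x$loglik, 2), ", AIC = ", round(x$aic, 1),
      ", CV accuracy = ", round(x$cv_accuracy, 3), "\n", sep = "")
  invisible(x)
}

#' Prediction entropy (bits)
#'
#' Shannon entropy of a three-way choice probability vector,
#' `H = -sum p log2 p` with `0 log 0 = 0`; the model's measure of choice
#' uncertainty, between 0 (deterministic) and `log2(3)` (uniform).
#'
#' @param p Probability vector summing to 1, or a matrix with one
#'   distribution per row.
#' @return Entropy in bits (vector if `p` is a matrix).
#' @export
prediction_entropy <- function(p) {
  if (is.null(dim(p))) p <- matrix(p, nrow = 1L)
  if (any(p < -1e-9) || any(abs(rowSums(p) - 1) > 1e-6))
    stop("`p` must be non-negative and sum to 1", call. = FALSE)
  pl <- ifelse(p > 0, p * log2(p), 0)
  h <- -rowSums(pl)
  pmin(pmax(h, 0), log2(ncol(p)))
}

#' Cross-validated accuracy of the simpler predictors
#'
#' Held-out accuracy of the closest-target rule (`w = 0.5`, no free
#' parameter) and the weighted rule (weight fitted on the training folds),
#' using the same contiguous folds as [fit_glm()] so the three model tiers
#' are comparable.
#'
#' @param cycles A `ccf_cycles` frame.
#' @param model `"closest"` or `"weighted"`.
#' @param k_folds Number of contiguous folds.
#' @return Mean held-out accuracy (fraction).
#' @export
cv_accuracy_rule <- function(cycles, model = c("closest", "weighted"),
                             k_folds = 5) {
  model <- match.arg(model)
  n <- nrow(cycles)
  d <- relevant_distances(cycles)
  fold <- cut(seq_len(n), breaks = k_folds, labels = FALSE)
  acc <- numeric(k_folds)
  for (f in seq_len(k_folds)) {
    te <- fold == f
    w <- if (model == "closest") 0.5 else as.numeric(fit_weight(cycles[!te, ]))
    acc[f] <- mean(predict_weighted(d[te, ], w) == cycles$target_kind[te])
  }
  mean(acc)
}

#' Expected accuracy of the uniform random baseline
#'
#' A predictor drawing uniformly among the three live targets is correct
#' with probability exactly 1/3 on every cycle, whatever the outcome
#' distribution; the expected accuracy over any cycle set is exactly 1/3.
#'
#' @param outcomes Character vector of observed kinds (its length is the
#'   only thing that matters).
#' @return Expected accuracy (exactly 1/3).
#' @export
uniform_baseline_accuracy <- function(outcomes) {
  n <- length(outcomes)
  if (n == 0L) stop("no outcomes", call. = FALSE)
  mean(rep(1 / 3, n))
}

#' Wald and sign-consistency inference across dyads
#'
#' Collects each coefficient's Wald p-values across per-dyad fits, adjusts
#' them per coefficient across the dyads with the Benjamini-Hochberg
#' procedure, and tests the sign consistency of the significant
#' coefficients with an exact two-sided binomial test against 0.5.
#'
#' @param fits List of `ccf_choice_fit` objects (one per dyad).
#' @param alpha Significance level applied to the adjusted p-values.
#' @return A data frame with one row per coefficient: `n_significant`,
#'   `n_positive` (among significant), `binom_p`, and list-columns are
#'   avoided by attaching the adjusted p-value matrix as attribute
#'   `"bh_p"` (dyads x coefficients).
#' @export
coefficient_tests <- function(fits, alpha = 0.05) {
  stopifnot(length(fits) >= 1L)
  pmat <- t(vapply(fits, function(f) f$wald_p, numeric(length(fits[[1L]]$theta))))
  tmat <- t(vapply(fits, function(f) f$theta, numeric(length(fits[[1L]]$theta))))
  colnames(pmat) <- colnames(tmat) <- names(fits[[1L]]$theta)
  bh <- apply(pmat, 2L, function(p) {
    adj <- rep(NA_real_, length(p))
    ok <- !is.na(p)
    adj[ok] <- stats::p.adjust(p[ok], method = "BH")
    adj
  })
  if (is.null(dim(bh))) bh <- matrix(bh, nrow = 1L, dimnames = list(NULL, colnames(pmat)))
  res <- data.frame(
    coefficient = colnames(pmat),
    n_significant = NA_integer_, n_positive = NA_integer_,
    binom_p = NA_real_, stringsAsFactors = FALSE
  )
  for (i in seq_len(ncol(pmat))) {
    sig <- which(!is.na(bh[, i]) & bh[, i] < alpha)
    res$n_significant[i] <- length(sig)
    res$n_positive[i] <- sum(tmat[sig, i] > 0)
    if (length(sig) > 0L)
      res$binom_p[i] <- stats::binom.test(res$n_positive[i], length(sig),
                                          p = 0.5)$p.value
  }
  attr(res, "bh_p") <- bh
  attr(res, "theta") <- tmat
  res
}

#' Moving-average FST of model predictions
#'
#' The moving-average fraction of single targets implied by a vector of
#' predicted kinds, on the same trailing windows as [fst_timecourse()];
#' used to compare how closely a model's predictions track the dyad's
#' actual FST fluctuations (30-s windows in the study's analysis).
#'
#' @param cycles A `ccf_cycles` frame.
#' @param predicted Character vector of predicted kinds aligned with
#'   `cycles` rows (or with a tail subset, matched by length).
#' @param window Window (s).
#' @return Data frame `t_s`, `fst` of the prediction.
#' @export
predicted_fst_series <- function(cycles, predicted, window = 30) {
  n_skip <- nrow(cycles) - length(predicted)
  stopifnot(n_skip >= 0L)
  cy <- cycles[(n_skip + 1L):nrow(cycles), ]
  fake <- cy
  fake$target_kind <- predicted
  fst_timecourse(fake, window)
}
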