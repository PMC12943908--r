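#' Filter configuration for the modified Kalman filter
#'
#' The filter carries the three-state vector `[p, v, a]` (displacement m,
#' velocity m/s, acceleration m/s^2) under the constant-acceleration
#' kinematic transition with sampling interval `dt` and observes the
#' acceleration component only (`H = [0 0 1]`). Two modifications sit on
#' top of the textbook filter: transient gain regulation triggered by
#' acceleration zero-crossings, and a sign-consistency rule on the
#' reported displacement.
#'
#' Gain regulation rescales the effective measurement variance for
#' `boost_samples` updates after a crossing. The default mode,
#' `"attenuate"`, multiplies R by `boost_factor` so the filter coasts on
#' its kinematic model through the gait-event transient (heel-strike
#' ringing concentrates at sign changes of the acceleration); the
#' `"amplify"` mode divides R by `boost_factor`, which provably moves the
#' gain toward the measurement and speeds convergence of the acceleration
#' state (in the `boost_factor -> Inf` limit the posterior acceleration
#' equals the measurement exactly).
#'
#' @param dt Sampling interval in seconds (default 0.02).
#' @param Q 3x3 process-noise covariance (default `diag(1e-6, 1e-4, 1e-2)`).
#' @param R Scalar measurement-noise variance, > 0 (default 0.05).
#' @param x0 Initial state 3-vector (default zeros).
#' @param P0 Initial 3x3 covariance (default identity).
#' @param boost_factor Gain-regulation multiplier >= 1 (default 10);
#'   in `"amplify"` mode, `Inf` is the zero-measurement-noise limit.
#' @param boost_samples Number of updates boosted after a zero-crossing
#'   (default 3; 0 disables boosting).
#' @param boost_mode `"attenuate"` (default) or `"amplify"`; see Details.
#' @param sign_flip_enabled Apply the displacement sign-consistency rule
#'   to the reported displacement trajectory (default TRUE).
#' @param calibration Multiplier applied to per-stride displacement when
#'   converting to stride length (default 1).
#' @param full_ca_transition If TRUE use the full constant-acceleration
#'   discretization with the 1/2*dt^2 coupling of acceleration into
#'   displacement; the default transition omits that term (`p <- p + dt*v`).
#' @return An object of class `filter_config`.
#' @export
filter_config <- function(dt = 0.02,
                          Q = diag(c(1e-6, 1e-4, 1e-2)),
                          R = 0.05,
                          x0 = c(0, 0, 0),
                          P0 = diag(3),
                          boost_factor = 10,
                          boost_samples = 3L,
                          boost_mode = c("attenuate", "amplify"),
                          sign_flip_enabled = TRUE,
                          calibration = 1.0,
                          full_ca_transition = FALSE) {
  Q <- as.matrix(Q); P0 <- as.matrix(P0)
  if (dt <= 0) stop("dt must be > 0")
  if (!(R > 0)) stop("R must be > 0")
  if (!all(dim(Q) == c(3L, 3L)) || !all(dim(P0) == c(3L, 3L)))
    stop("Q and P0 must be 3x3")
  if (min(eigen(Q, symmetric = TRUE, only.values = TRUE)$values) < -1e-10)
    stop("Q must be positive semi-definite")
  if (boost_factor < 1) stop("boost_factor must be >= 1")
  if (boost_samples < 0) stop("boost_samples must be >= 0")
  boost_mode <- match.arg(boost_mode)
  A <- if (full_ca_transition)
    matrix(c(1, dt, dt^2 / 2, 0, 1, dt, 0, 0, 1), 3, 3, byrow = TRUE)
  else
    matrix(c(1, dt, 0, 0, 1, dt, 0, 0, 1), 3, 3, byrow = TRUE)
  structure(list(dt = dt, Q = Q, R = R, x0 = as.numeric(x0), P0 = P0,
                 boost_factor = boost_factor,
                 boost_samples = as.integer(boost_samples),
                 boost_mode = boost_mode,
                 sign_flip_enabled = isTRUE(sign_flip_enabled),
                 calibration = calibration,
                 full_ca_transition = isTRUE(full_ca_transition),
                 A = A,
                 # control matrix of the CA discretization; the control
                 # input is identically zero, B is kept for completeness
                 B = c(dt^2 / 2, dt, 1),
                 H = c(0, 0, 1)),
            class = "filter_config")
}

#' Construct a filter state
#'
#' @param x State 3-vector `[p, v, a]`.
#' @param P 3x3 covariance; must be symmetric (within 1e-10) and positive
#'   semi-definite (eigenvalue floor -1e-10).
#' @return An object of class `filter_state`.
#' @export
filter_state <- function(x, P) {
  x <- as.numeric(x); P <- as.matrix(P)
  if (length(x) != 3L || !all(dim(P) == c(3L, 3L)))
    stop("state must be a 3-vector with a 3x3 covariance")
  if (max(abs(P - t(P))) > 1e-10) stop("covariance not symmetric")
  if (min(eigen((P + t(P)) / 2, symmetric = TRUE,
                only.values = TRUE)$values) < -1e-10)
    stop("covariance not positive semi-definite")
  structure(list(x = x, P = P), class = "filter_state")
}

#' Kalman prediction step
#'
#' `x_prior = A x`, `P_prior = A P A^T + Q`. The control input is fixed to
#' zero, so `B u` contributes nothing.
#'
#' @param state A [filter_state()].
#' @param cfg A [filter_config()].
#' @return The a-priori [filter_state()].
#' @export
kf_predict <- function(state, cfg) {
  stopifnot(inherits(state, "filter_state"), inherits(cfg, "filter_config"))
  A <- cfg$A
  filter_state(A %*% state$x, A %*% state$P %*% t(A) + cfg$Q)
}

#' Kalman measurement update
#'
#' `K = P_prior H^T / (H P_prior H^T + R_eff)` where at boosted steps
#' `R_eff = R * boost_factor` (`"attenuate"` mode, default) or
#' `R_eff = R / boost_factor` (`"amplify"` mode), followed by the standard
#' state and covariance updates; the returned covariance is re-symmetrized.
#'
#' @param prior The a-priori [filter_state()].
#' @param z Measured acceleration (m/s^2).
#' @param cfg A [filter_config()].
#' @param boosted Whether this update falls inside a zero-crossing boost
#'   window.
#' @return The a-posteriori [filter_state()].
#' @export
kf_update <- function(prior, z, cfg, boosted = FALSE) {
  stopifnot(inherits(prior, "filter_state"), inherits(cfg, "filter_config"))
  R_eff <- if (!boosted) cfg$R
           else if (identical(cfg$boost_mode, "amplify"))
             cfg$R / cfg$boost_factor
           else cfg$R * cfg$boost_factor
  S <- prior$P[3L, 3L] + R_eff
  if (S <= 0) stop("innovation variance <= 0: broken filter configuration")
  K <- prior$P[, 3L] / S
  x <- prior$x + K * (z - prior$x[3L])
  P <- prior$P - K %o% prior$P[3L, ]
  P <- (P + t(P)) / 2
  filter_state(x, P)
}

#' Acceleration zero-crossing detector
#'
#' TRUE exactly when the two consecutive measurements straddle zero
#' (`z_prev * z_curr < 0`, strict: exact zeros do not trigger).
#'
#' @param z_prev,z_curr Consecutive acceleration measurements.
#' @return Logical flag.
#' @export
detect_zero_crossing <- function(z_prev, z_curr) {
  z_prev * z_curr < 0
}

#' Displacement sign-consistency rule
#'
#' If the current and previous displacement values have strictly opposite
#' signs, the current value's sign is flipped to match its predecessor,
#' preserving magnitude; it is a logical check only and touches neither the
#' gain nor the covariance.
#'
#' @param p_curr,p_prev Current and previous displacement values (m).
#' @return Corrected current displacement.
#' @export
sign_flip_correct <- function(p_curr, p_prev) {
  if (p_curr * p_prev < 0) -p_curr else p_curr
}

#' Run the modified Kalman filter over an acceleration sequence
#'
#' For each sample: predict; test the current measurement against the
#' previous one for a zero-crossing and, on a crossing, regulate the gain
#' for the next `boost_samples` updates (the triggering step included);
#' update. The displacement sign-consistency rule, when enabled, is a
#' logical check applied sequentially to the reported displacement
#' trajectory — magnitudes are preserved and the filter recursion, gain
#' and covariance are untouched — so the emitted displacement sequence
#' never contains an adjacent pair with strictly negative product. With
#' `boost_factor = 1` (or `boost_samples = 0`) and the sign rule disabled
#' the trajectory is identical to a textbook linear Kalman filter with the
#' same `A`, `H`, `Q`, `R`.
#'
#' @param z Numeric vector of acceleration measurements (length >= 2).
#' @param cfg A [filter_config()].
#' @return An object of class `mekf`: list with `states` (n x 3 matrix of
#'   posterior `[p, v, a]`), `P` (3 x 3 x n array of posterior covariances),
#'   `boosted` and `crossing` logical vectors, the measurements `z` and the
#'   `cfg`.
#' @export
run_mekf <- function(z, cfg = filter_config()) {
  stopifnot(inherits(cfg, "filter_config"))
  z <- as.numeric(z)
  n <- length(z)
  if (n < 2L) stop("need at least 2 measurements")
  states <- matrix(0, n, 3L,
                   dimnames = list(NULL, c("p", "v", "a")))
  Parr <- array(0, c(3L, 3L, n))
  boosted <- logical(n)
  crossing <- logical(n)
  st <- filter_state(cfg$x0, cfg$P0)
  boost_left <- 0L
  for (k in seq_len(n)) {
    prior <- kf_predict(st, cfg)
    if (k > 1L && detect_zero_crossing(z[k - 1L], z[k])) {
      crossing[k] <- TRUE
      boost_left <- cfg$boost_samples
    }
    boosted[k] <- boost_left > 0L
    st <- kf_update(prior, z[k], cfg, boosted = boosted[k])
    if (boost_left > 0L) boost_left <- boost_left - 1L
    states[k, ] <- st$x
    Parr[, , k] <- st$P
  }
  if (cfg$sign_flip_enabled) {
    p_prev <- cfg$x0[1L]
    for (k in seq_len(n)) {
      states[k, 1L] <- sign_flip_correct(states[k, 1L], p_prev)
      p_prev <- states[k, 1L]
    }
  }
  structure(list(states = states, P = Parr, boosted = boosted,
                 crossing = crossing, z = z, cfg = cfg),
            class = "mekf")
}

#' @export
print.mekf <- function(x, ...) {
  cat(sprintf(paste0("<mekf> %d samples filtered (dt = %g s)\n",
                     "  boost: factor %g for %d samples at %d",
                     " zero-crossings; sign rule %s\n",
                     "  final state: p = %.4f m, v = %.4f m/s,",
                     " a = %.4f m/s^2\n"),
              nrow(x$states), x$cfg$dt, x$cfg$boost_factor,
              x$cfg$boost_samples, sum(x$crossing),
              if (x$cfg$sign_flip_enabled) "on" else "off",
              x$states[nrow(x$states), 1L],
              x$states[nrow(x$states), 2L],
              x$states[nrow(x$states), 3L]))
  invisible(x)
}

#' @export
fitted.mekf <- function(object, ...) object$states[, "a"]

#' @export
residuals.mekf <- function(object, ...) object$z - object$states[, "a"]

#' @export
coef.mekf <- function(object, ...) object$states

#' Plot a filtered trajectory
#'
#' Two panels: measured vs. filtered acceleration (zero-crossing boosts
#' marked) and the displacement/velocity states.
#'
#' @param x An `mekf` object.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.mekf <- function(x, ...) {
  t <- (seq_len(nrow(x$states)) - 1) * x$cfg$dt
  op <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 1.5, 1))
  on.exit(graphics::par(op))
  graphics::plot(t, x$z, type = "l", col = "grey60",
                 xlab = "time [s]", ylab = "acceleration [m/s^2]", ...)
  graphics::lines(t, x$states[, "a"], col = "firebrick")
  if (any(x$boosted))
    graphics::points(t[x$boosted], x$z[x$boosted], pch = 16, cex = 0.4,
                     col = "dodgerblue")
  graphics::legend("topright", bty = "n", lty = c(1, 1, NA),
                   pch = c(NA, NA, 16), cex = 0.8,
                   col = c("grey60", "firebrick", "dodgerblue"),
                   legend = c("measured", "filtered", "boosted"))
  graphics::plot(t, x$states[, "p"], type = "l", col = "forestgreen",
                 xlab = "time [s]", ylab = "p [m] / v [m/s]")
  graphics::lines(t, x$states[, "v"], col = "purple")
  graphics::legend("topright", bty = "n", lty = 1, cex = 0.8,
                   col = c("forestgreen", "purple"),
                   legend = c("displacement", "velocity"))
  invisible(x)
}

#' Stride length from a filtered state trajectory
#'
#' The per-stride length is the absolute displacement accumulated by the
#' filter over the segment, `|p_end - p_start|`, times the calibration
#' factor.
#'
#' @param states An `mekf` object or an n x 3 state matrix (>= 3 rows).
#' @param cfg A [filter_config()] supplying the calibration factor.
#' @return Stride length in meters (non-negative).
#' @export
stride_length_from_states <- function(states, cfg = filter_config()) {
  if (inherits(states, "mekf")) states <- states$states
  states <- as.matrix(states)
  if (nrow(states) < 3L) stop("need >= 3 states for a stride")
  unname(abs(states[nrow(states), 1L] - states[1L, 1L]) * cfg$calibration)
}
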