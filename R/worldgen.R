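#' Deterministic touch rule
#'
#' Touch is delivered when the Euclidean distance between hand and visual
#' stimulus is strictly below 0.15 m, roughly the centre-to-centre
#' distance at which hand-object contact occurs.
#'
#' @param hand_x,hand_y,vis_x,vis_y coordinates (metres), vectorized.
#' @param radius contact radius in metres.
#' @return Logical vector.
#' @export
touch_rule <- function(hand_x, hand_y, vis_x, vis_y,
                       radius = .pps$touch_radius) {
  sqrt((hand_x - vis_x)^2 + (hand_y - vis_y)^2) < radius
}

.draw_gains <- function(n) runif(n, .pps$gain_range[1], .pps$gain_range[2])

.base_world <- function(n) {
  tibble(
    trial  = seq_len(n),
    hand_x = runif(n, .pps$hand_lo[1], .pps$hand_hi[1]),
    hand_y = runif(n, .pps$hand_lo[2], .pps$hand_hi[2]),
    vis_x  = runif(n, .pps$vis_lo[1], .pps$vis_hi[1]),
    vis_y  = runif(n, .pps$vis_lo[2], .pps$vis_hi[2]),
    gain_v = .draw_gains(n),
    gain_p = .draw_gains(n),
    gain_t = .draw_gains(n)
  )
}

#' Synthetic multisensory stimulus streams
#'
#' Generators for the trial streams used in training and testing. Hand
#' positions are uniform over the 1.2 x 0.6 m workspace in front of the
#' trunk, visual stimuli uniform over 1.2 x 1.2 m, and each population's
#' gain is an independent uniform draw on \[4, 10\] per trial.
#'
#' * `sample_constrained()`: body-constrained statistics; touch follows the
#'   geometry via [touch_rule()] (about 4.5% of trials).
#' * `sample_unconstrained()`: control; touch is Bernoulli(`p_touch`),
#'   independent of geometry, with identical marginals otherwise.
#' * `sample_handvision()`: adds a second visual population coding hand
#'   position: congruent with proprioception (probability
#'   `1 - p_occluded - p_dissociated`), suppressed (occlusion), or an
#'   independent uniform position (another person's hand). Categories are
#'   mutually exclusive, one categorical draw per trial.
#' * `sample_joint()`: proprioception as shoulder/elbow joint angles,
#'   uniform over \eqn{\theta_1 \in [-\pi/4, \pi/2]},
#'   \eqn{\theta_2 \in [-\pi/2, 0]}; hand position follows from
#'   [forward_kinematics()].
#' * `sample_gaze()`: additionally draws a gaze angle uniform on
#'   \eqn{[-\pi/4, \pi/4]}; the visual stimulus is uniform in eye-centred
#'   coordinates and its body-centred position follows from
#'   [gaze_rotate()]. Touch always acts on body-centred coordinates.
#'
#' @param n number of trials.
#' @param seed optional integer; when given, the stream is reproducible.
#' @param p_touch touch probability for the unconstrained control.
#' @param p_occluded,p_dissociated category probabilities for the
#'   hand-vision variant (must sum to at most 1).
#' @return A tibble with one row per trial: positions (m), per-population
#'   gains, and the logical `touch` flag; variant-specific columns as
#'   described above.
#' @examples
#' w <- sample_constrained(1000, seed = 1)
#' mean(w$touch)
#' @name worldgen
NULL

#' @rdname worldgen
#' @export
sample_constrained <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  w <- .base_world(n)
  w$touch <- touch_rule(w$hand_x, w$hand_y, w$vis_x, w$vis_y)
  w
}

#' @rdname worldgen
#' @export
sample_unconstrained <- function(n, seed = NULL, p_touch = 0.05) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(p_touch >= 0, p_touch <= 1)
  w <- .base_world(n)
  w$touch <- runif(n) < p_touch
  w
}

#' @rdname worldgen
#' @export
sample_handvision <- function(n, seed = NULL, p_occluded = 0.25,
                              p_dissociated = 0.25) {
  if (!is.null(seed)) set.seed(seed)
  if (p_occluded < 0 || p_dissociated < 0 || p_occluded + p_dissociated > 1) {
    abort("category probabilities must be nonnegative and sum to at most 1")
  }
  w <- .base_world(n)
  w$touch <- touch_rule(w$hand_x, w$hand_y, w$vis_x, w$vis_y)
  u <- runif(n)
  w$hv_mode <- ifelse(u < p_occluded, "occluded",
                      ifelse(u < p_occluded + p_dissociated, "dissociated",
                             "congruent"))
  w$hv_x <- w$hand_x
  w$hv_y <- w$hand_y
  dis <- w$hv_mode == "dissociated"
  w$hv_x[dis] <- runif(sum(dis), .pps$hand_lo[1], .pps$hand_hi[1])
  w$hv_y[dis] <- runif(sum(dis), .pps$hand_lo[2], .pps$hand_hi[2])
  occ <- w$hv_mode == "occluded"
  w$hv_x[occ] <- NA_real_
  w$hv_y[occ] <- NA_real_
  w$gain_hv <- .draw_gains(n)
  w
}

#' Two-link forward kinematics
#'
#' Hand position from shoulder (\eqn{\theta_1}) and elbow (\eqn{\theta_2})
#' angles for an arm of 0.3 m and forearm of 0.35 m (to the hand centre):
#' \eqn{x = 0.3\sin\theta_1 + 0.35\sin(\theta_1+\theta_2)},
#' \eqn{y = 0.3\cos\theta_1 + 0.35\cos(\theta_1+\theta_2)}.
#' \eqn{\theta_1 = 0} points the arm straight ahead; \eqn{\theta_2 = 0} is
#' full extension.
#'
#' @param theta1,theta2 angles in radians, vectorized.
#' @return A tibble with columns `x`, `y` (metres).
#' @export
forward_kinematics <- function(theta1, theta2) {
  L <- .pps$arm_lengths
  tibble(
    x = L[1] * sin(theta1) + L[2] * sin(theta1 + theta2),
    y = L[1] * cos(theta1) + L[2] * cos(theta1 + theta2)
  )
}

#' Eye-centred to body-centred coordinates
#'
#' Rotates an eye-centred position by the negative gaze angle about the
#' body's vertical axis, yielding trunk-centred coordinates: with gaze
#' angle \eqn{\theta}, the body-centred position is
#' \eqn{R_z(-\theta)\,x_{eye}}.
#'
#' @param x,y eye-centred coordinates (metres), vectorized.
#' @param gaze gaze angle(s) in radians (0 = looking straight ahead).
#' @return A tibble with body-centred `x`, `y`.
#' @export
gaze_rotate <- function(x, y, gaze) {
  xb <- cos(gaze) * x + sin(gaze) * y
  yb <- -sin(gaze) * x + cos(gaze) * y
  tibble(x = xb, y = yb)
}

#' @rdname worldgen
#' @export
sample_joint <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  w <- tibble(
    trial  = seq_len(n),
    theta1 = runif(n, .pps$theta1_range[1], .pps$theta1_range[2]),
    theta2 = runif(n, .pps$theta2_range[1], .pps$theta2_range[2]),
    vis_x  = runif(n, .pps$vis_lo[1], .pps$vis_hi[1]),
    vis_y  = runif(n, .pps$vis_lo[2], .pps$vis_hi[2]),
    gain_v = .draw_gains(n),
    gain_p = .draw_gains(n),
    gain_t = .draw_gains(n)
  )
  hk <- forward_kinematics(w$theta1, w$theta2)
  w$hand_x <- hk$x
  w$hand_y <- hk$y
  w$touch <- touch_rule(w$hand_x, w$hand_y, w$vis_x, w$vis_y)
  w
}

#' @rdname worldgen
#' @export
sample_gaze <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  w <- sample_joint(n)
  w$gaze <- runif(n, .pps$gaze_range[1], .pps$gaze_range[2])
  w$gain_g <- .draw_gains(n)
  ## the uniform visual draw is eye-centred; body-centred coordinates
  ## (used by the touch rule) follow by rotating by the negative gaze angle
  w$vis_eye_x <- w$vis_x
  w$vis_eye_y <- w$vis_y
  body <- gaze_rotate(w$vis_eye_x, w$vis_eye_y, w$gaze)
  w$vis_x <- body$x
  w$vis_y <- body$y
  w$touch <- touch_rule(w$hand_x, w$hand_y, w$vis_x, w$vis_y)
  w
}
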