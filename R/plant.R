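#' Planar 3-DoF kinematic arm
#'
#' A three-segment articulated arm in the plane, anchored at the origin.
#' Joint angles are in radians, counter-clockwise positive, and cumulative
#' along the chain.  Each joint is driven by one read-out unit through an
#' affine map from the read-out rate range `[0, 1]` onto the joint's angle
#' limits.
#'
#' @param lengths segment lengths (3-vector, arbitrary units).
#' @param joint_limits 3x2 matrix of per-joint angle bounds (rad); row i is
#'   `c(lo, hi)` for joint i.
#' @return An object of class `arm_model`.
#' @export
arm_model <- function(lengths = c(1, 1, 1),
                      joint_limits = matrix(rep(c(-pi / 2, pi), each = 3), 3)) {
  stopifnot(length(lengths) == 3L, all(lengths > 0),
            is.matrix(joint_limits), dim(joint_limits) == c(3L, 2L),
            all(joint_limits[, 2] > joint_limits[, 1]))
  structure(list(lengths = as.numeric(lengths), joint_limits = joint_limits),
            class = "arm_model")
}

#' @export
print.arm_model <- function(x, ...) {
  cat(sprintf("Planar 3-DoF kinematic arm; segment lengths %s, reach %g\n",
              paste(format(x$lengths), collapse = ", "), sum(x$lengths)))
  invisible(x)
}

#' Map read-out rates to joint angles (and back)
#'
#' @param rates read-out rates, typically in `[0, 1]`.
#' @param arm an [arm_model()].
#' @return `rates_to_angles`: joint angles (rad); `angles_to_rates`: the
#'   inverse affine map.
#' @export
rates_to_angles <- function(rates, arm = arm_model()) {
  lo <- arm$joint_limits[, 1]
  hi <- arm$joint_limits[, 2]
  lo + rates * (hi - lo)
}

#' @rdname rates_to_angles
#' @param angles joint angles (rad).
#' @export
angles_to_rates <- function(angles, arm = arm_model()) {
  lo <- arm$joint_limits[, 1]
  hi <- arm$joint_limits[, 2]
  (angles - lo) / (hi - lo)
}

#' Forward kinematics of the planar arm
#'
#' @param angles 3-vector of joint angles (rad), or a T x 3 matrix of a
#'   trajectory.
#' @param arm an [arm_model()].
#' @return For a single posture, a list with `joints` (4 x 2 matrix of the
#'   base, two joints and end effector) and `end` (2-vector).  For a
#'   trajectory matrix, a T x 2 matrix of end-effector positions.
#' @examples
#' forward_kinematics(c(0, 0, 0))$end  # straight arm: (3, 0)
#' @export
forward_kinematics <- function(angles, arm = arm_model()) {
  if (is.matrix(angles)) {
    stopifnot(ncol(angles) == 3L)
    out <- t(apply(angles, 1L, function(a) forward_kinematics(a, arm)$end))
    colnames(out) <- c("x", "y")
    return(out)
  }
  stopifnot(length(angles) == 3L, all(is.finite(angles)))
  phi <- cumsum(angles)
  pts <- matrix(0, 4, 2)
  for (i in 1:3) {
    pts[i + 1, ] <- pts[i, ] + arm$lengths[i] * c(cos(phi[i]), sin(phi[i]))
  }
  list(joints = pts, end = pts[4, ])
}

#' Damped-least-squares inverse kinematics
#'
#' Iteratively solves for joint angles reaching a 2D point, warm-started
#' from `init` (so consecutive samples of a smooth curve yield a smooth
#' joint trajectory).
#'
#' @param target 2-vector (x, y).
#' @param arm an [arm_model()].
#' @param init initial joint angles.
#' @param damping damped-least-squares factor.
#' @param tol Cartesian convergence tolerance.
#' @param max_iter iteration cap.
#' @return 3-vector of joint angles.
#' @export
inverse_kinematics <- function(target, arm = arm_model(),
                               init = c(pi / 4, pi / 4, pi / 4),
                               damping = 0.1, tol = 1e-8, max_iter = 200) {
  if (sqrt(sum(target^2)) > sum(arm$lengths)) {
    stop(sprintf("target (%g, %g) outside arm reach %g",
                 target[1], target[2], sum(arm$lengths)))
  }
  q <- init
  lo <- arm$joint_limits[, 1]
  hi <- arm$joint_limits[, 2]
  for (iter in seq_len(max_iter)) {
    phi <- cumsum(q)
    # end-effector position and Jacobian of the cumulative-angle chain
    seg <- arm$lengths * cbind(cos(phi), sin(phi))
    p <- colSums(seg)
    err <- target - p
    if (sum(err^2) < tol^2) break
    J <- matrix(0, 2, 3)
    for (j in 1:3) {
      idx <- j:3
      J[1, j] <- -sum(arm$lengths[idx] * sin(phi[idx]))
      J[2, j] <- sum(arm$lengths[idx] * cos(phi[idx]))
    }
    dq <- crossprod(J, solve(J %*% t(J) + damping^2 * diag(2), err))
    q <- pmin(pmax(q + as.numeric(dq), lo), hi)
  }
  q
}

#' Catalogue of parametric 2D target shapes
#'
#' Closed planar curves used as rhythmic targets: a rounded-corner square,
#' a sideways figure-eight (Lissajous), and a moon-like crescent formed by
#' two circular arcs.  `shape_catalogue()` lists the available identifiers.
#'
#' @param shape_id one of `"square"`, `"figure8"`, `"moon"`, `"circle"`.
#' @param n_samples number of samples along the curve (uniform in phase).
#' @param center 2-vector, curve center.
#' @param scale overall size factor (half-extent, arm units).
#' @return `shape_curve`: an `n_samples` x 2 matrix tracing the closed
#'   curve (first point repeated at the end of the phase cycle is omitted;
#'   the curve is closed in the sense that sample n connects back to
#'   sample 1).
#' @export
shape_curve <- function(shape_id, n_samples = 200, center = c(1.2, 1.2),
                        scale = 0.45) {
  ph <- seq(0, 2 * pi, length.out = n_samples + 1L)[seq_len(n_samples)]
  xy <- switch(shape_id,
    square = {
      # rounded square traced at constant phase speed; corner radius 0.25
      r <- 0.25
      sq <- function(t) {
        c8 <- function(v) sign(v) * pmin(abs(v) / (1 - r), 1)
        cbind(c8(cos(t)), c8(sin(t)))
      }
      raw <- sq(ph)
      raw + r * cbind(cos(ph), sin(ph))
    },
    figure8 = cbind(sin(ph), 0.5 * sin(2 * ph)),
    moon = {
      # crescent: outer arc of the unit circle plus an inner arc bent inward
      half <- ph < pi
      x <- ifelse(half, cos(pi / 2 + ph * 1.0), cos(pi / 2 - (ph - pi)))
      y <- ifelse(half, sin(pi / 2 + ph * 1.0), 0.35 + 0.65 * sin(pi / 2 - (ph - pi)))
      cbind(x, y)
    },
    circle = cbind(cos(ph), sin(ph)),
    stop(sprintf("unknown shape '%s'; see shape_catalogue()", shape_id))
  )
  xy <- sweep(xy, 2L, colMeans(xy))    # center the raw curve
  sweep(xy * scale, 2L, center, `+`)
}

#' @rdname shape_curve
#' @export
shape_catalogue <- function() c("square", "figure8", "moon", "circle")

#' Build a motor target task
#'
#' Converts a catalogue shape (rhythmic task) or a fixed posture
#' (end-point task) into a joint-angle target series over one task window,
#' via damped-least-squares inverse kinematics warm-started sample to
#' sample.
#'
#' @param shape_id catalogue shape identifier (rhythmic tasks).
#' @param n_samples samples over the task window.
#' @param arm an [arm_model()].
#' @param center,scale placement of the shape in the workspace.
#' @return A list of class `target_task` with `kind`, `angles`
#'   (n_samples x 3), `xy` (the Cartesian target curve) and `rates`
#'   (angles mapped through [angles_to_rates()]).
#' @export
make_target <- function(shape_id, n_samples = 200, arm = arm_model(),
                        center = c(1.2, 1.2), scale = 0.45) {
  xy <- shape_curve(shape_id, n_samples, center = center, scale = scale)
  ang <- matrix(0, n_samples, 3)
  q <- inverse_kinematics(xy[1, ], arm)
  for (i in seq_len(n_samples)) {
    q <- inverse_kinematics(xy[i, ], arm, init = q)
    ang[i, ] <- q
  }
  structure(list(kind = "rhythmic", shape_id = shape_id, angles = ang, xy = xy,
                 rates = t(apply(ang, 1L, angles_to_rates, arm = arm)),
                 arm = arm),
            class = "target_task")
}

#' @rdname make_target
#' @param posture 3-vector of joint angles (rad) for an end-point task.
#' @export
make_posture_target <- function(posture, n_samples = 200, arm = arm_model()) {
  stopifnot(length(posture) == 3L,
            all(posture >= arm$joint_limits[, 1]),
            all(posture <= arm$joint_limits[, 2]))
  ang <- matrix(posture, n_samples, 3, byrow = TRUE)
  structure(list(kind = "endpoint", shape_id = "posture", angles = ang,
                 xy = forward_kinematics(ang, arm),
                 rates = t(apply(ang, 1L, angles_to_rates, arm = arm)),
                 arm = arm),
            class = "target_task")
}

#' Normalized root-mean-square error
#'
#' Per-dimension RMSE divided by the target's range (max - min), averaged
#' over dimensions.  The range normalizer makes the measure comparable
#' across joints with different excursions and invariant to jointly
#' translating prediction and target.
#'
#' @param pred,target numeric matrices (T x D) or vectors of equal shape.
#' @param range_floor optional lower bound for the normalizer: dimensions
#'   whose target range falls below it are normalized by the floor instead
#'   (used for end-point tasks, whose targets are constant).  With the
#'   default 0, a zero-range target dimension is an error.
#' @return Non-negative scalar.
#' @export
nrmse <- function(pred, target, range_floor = 0) {
  pred <- as.matrix(pred)
  target <- as.matrix(target)
  stopifnot(all(dim(pred) == dim(target)))
  rmse <- sqrt(colMeans((pred - target)^2))
  rng <- apply(target, 2L, function(v) diff(range(v)))
  if (any(rng <= 0) && range_floor <= 0) {
    stop("target has zero range in some dimension; rhythmic NRMSE is undefined")
  }
  mean(rmse / pmax(rng, range_floor))
}
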