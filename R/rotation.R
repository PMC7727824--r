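#' Compose the two-axis gimbal rotation
#'
#' Builds the rotation matrix mapping inner-frame (sample) coordinates to lab
#' coordinates for a two-axis gimbal. The convention, used consistently
#' throughout the package, is: lab frame z-up with gravity along -z; the outer
#' axis is the lab x-axis, the inner axis is the y-axis of the outer frame.
#' Hence `R = R_x(alpha) %*% R_y(beta)`, where `R_x`, `R_y` are right-handed
#' elementary rotations.
#'
#' @param alpha Outer-axis angle in radians (unwrapped real number).
#' @param beta Inner-axis angle in radians.
#' @return A 3x3 orthonormal rotation matrix with determinant +1.
#' @examples
#' compose_rotation(0, 0)            # identity
#' compose_rotation(pi, 0)           # half turn about x: diag(1, -1, -1)
#' @export
compose_rotation <- function(alpha, beta) {
  if (!is.finite(alpha) || !is.finite(beta))
    stop("compose_rotation: angles must be finite")
  ca <- cos(alpha); sa <- sin(alpha)
  cb <- cos(beta);  sb <- sin(beta)
  matrix(c(
    cb,        0,  sb,
    sa * sb,  ca, -sa * cb,
    -ca * sb,  sa,  ca * cb
  ), nrow = 3, byrow = TRUE)
}

#' Gravity direction in the sample frame
#'
#' Expresses the (unit) gravity direction in the rotating inner frame for a
#' gimbal pose: `u = t(R) %*% c(0, 0, -1)`. In closed form under the package
#' convention, `u = (cos(alpha) sin(beta), -sin(alpha), -cos(alpha) cos(beta))`.
#'
#' @param alpha,beta Gimbal angles in radians; vectors of equal length are
#'   accepted and processed elementwise.
#' @return A numeric 3-vector for scalar input, otherwise an `n x 3` matrix of
#'   unit rows.
#' @export
gravity_direction <- function(alpha, beta) {
  stopifnot_finite(alpha, "alpha"); stopifnot_finite(beta, "beta")
  u <- cbind(cos(alpha) * sin(beta), -sin(alpha), -cos(alpha) * cos(beta))
  if (length(alpha) == 1L && length(beta) == 1L) drop(u) else u
}

#' Gimbal angles realizing a gravity direction
#'
#' Inverse kinematics of [gravity_direction()]: finds gimbal angles whose
#' sample-frame gravity direction equals `u`. Of the two solution branches the
#' one nearest (in unwrapped angle space) to `current` is returned. At gimbal
#' lock (`|u_y| = 1` under the package convention, where the inner angle is
#' redundant) the inner angle keeps its current value.
#'
#' @param u Unit 3-vector (norm 1 within 1e-6), the desired gravity direction
#'   in the sample frame.
#' @param current Numeric 2-vector `c(alpha, beta)`, the pose from which the
#'   move starts. Defaults to `c(0, 0)`.
#' @return Numeric 2-vector `c(alpha, beta)` in radians (unwrapped, i.e. chosen
#'   on the branch closest to `current`).
#' @export
inverse_kinematics <- function(u, current = c(0, 0)) {
  if (length(u) != 3L || !all(is.finite(u)))
    stop("inverse_kinematics: 'u' must be a finite 3-vector")
  if (abs(vec_norm(u) - 1) > 1e-6)
    stop("inverse_kinematics: 'u' must be a unit vector (|u| = 1 within 1e-6)")
  u <- u / vec_norm(u)
  if (1 - u[2]^2 < 1e-24) {            # gimbal lock: alpha = -/+ pi/2, beta free
    a <- unwrap_to(asin(-u[2]), current[1])
    return(c(a, current[2]))
  }
  a1 <- asin(max(-1, min(1, -u[2])))
  b1 <- atan2(u[1], -u[3])
  cand <- rbind(c(a1, b1), c(pi - a1, b1 + pi))
  best <- NULL; best_d <- Inf
  for (k in 1:2) {
    a <- unwrap_to(cand[k, 1], current[1])
    b <- unwrap_to(cand[k, 2], current[2])
    d <- (a - current[1])^2 + (b - current[2])^2
    if (d < best_d) { best_d <- d; best <- c(a, b) }
  }
  best
}

# Shift `angle` by a multiple of 2*pi so that it lies nearest to `ref`.
unwrap_to <- function(angle, ref) {
  angle + 2 * pi * round((ref - angle) / (2 * pi))
}
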