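#' Kinematics of an off-center sample point
#'
#' Computes lab-frame position, velocity and acceleration of a sample mounted
#' at offset `r_pc` from the gimbal pivot. The pivot itself is fixed (the
#' benchtop machine rotates but does not translate), so the sample position is
#' `r_c(t) = R(t) %*% r_pc`.
#'
#' The analytic method assembles the body-frame angular velocity
#' `omega = (alpha_rate * cos(beta), beta_rate, alpha_rate * sin(beta))`
#' (the inner-frame image of the outer axis plus the inner axis) and its
#' analytic time derivative from the stored rates and accelerations, then
#' evaluates `a = R (omega x (omega x r) + domega x r)` — the centripetal plus
#' Euler terms of rotation about a fixed point. The finite-difference method
#' applies central differences to the position series and exists to
#' cross-validate the analytic route; its error shrinks as O(dt^2).
#'
#' @param traj An [trajectory()] object with at least 5 states.
#' @param sample An [sample_spec()] object.
#' @param method `"analytic"` (default) or `"finite_difference"`.
#' @return An object of class `mgs_kinematics`: a data frame with columns
#'   `t, x, y, z, vx, vy, vz, ax, ay, az` (SI units).
#' @export
point_kinematics <- function(traj, sample,
                             method = c("analytic", "finite_difference")) {
  method <- match.arg(method)
  if (!inherits(traj, "mgs_trajectory")) stop("point_kinematics: 'traj' must be a trajectory")
  if (!inherits(sample, "mgs_sample_spec")) stop("point_kinematics: bad 'sample'")
  n <- nrow(traj)
  if (n < 5L) stop("point_kinematics: trajectory too short (need >= 5 states)")
  dt <- attr(traj, "dt")
  r <- sample$offset
  ca <- cos(traj$alpha); sa <- sin(traj$alpha)
  cb <- cos(traj$beta);  sb <- sin(traj$beta)
  # rotation matrix rows (R maps body -> lab); R = R_x(alpha) R_y(beta)
  R11 <- cb;        R12 <- 0;  R13 <- sb
  R21 <- sa * sb;   R22 <- ca; R23 <- -sa * cb
  R31 <- -ca * sb;  R32 <- sa; R33 <- ca * cb
  pos <- cbind(
    R11 * r[1] + R12 * r[2] + R13 * r[3],
    R21 * r[1] + R22 * r[2] + R23 * r[3],
    R31 * r[1] + R32 * r[2] + R33 * r[3])
  # body angular velocity and its analytic derivative
  w1 <- traj$alpha_rate * cb
  w2 <- traj$beta_rate
  w3 <- traj$alpha_rate * sb
  dw1 <- traj$alpha_acc * cb - traj$alpha_rate * traj$beta_rate * sb
  dw2 <- traj$beta_acc
  dw3 <- traj$alpha_acc * sb + traj$alpha_rate * traj$beta_rate * cb
  # v_body = omega x r
  vb <- cbind(w2 * r[3] - w3 * r[2],
              w3 * r[1] - w1 * r[3],
              w1 * r[2] - w2 * r[1])
  vel <- cbind(R11 * vb[, 1] + R12 * vb[, 2] + R13 * vb[, 3],
               R21 * vb[, 1] + R22 * vb[, 2] + R23 * vb[, 3],
               R31 * vb[, 1] + R32 * vb[, 2] + R33 * vb[, 3])
  if (method == "analytic") {
    # a_body = omega x (omega x r) + domega x r
    ab <- cbind(w2 * vb[, 3] - w3 * vb[, 2] + dw2 * r[3] - dw3 * r[2],
                w3 * vb[, 1] - w1 * vb[, 3] + dw3 * r[1] - dw1 * r[3],
                w1 * vb[, 2] - w2 * vb[, 1] + dw1 * r[2] - dw2 * r[1])
    acc <- cbind(R11 * ab[, 1] + R12 * ab[, 2] + R13 * ab[, 3],
                 R21 * ab[, 1] + R22 * ab[, 2] + R23 * ab[, 3],
                 R31 * ab[, 1] + R32 * ab[, 2] + R33 * ab[, 3])
  } else {
    acc <- apply(pos, 2, central_second_derivative, dt = dt)
  }
  structure(data.frame(t = traj$t,
                       x = pos[, 1], y = pos[, 2], z = pos[, 3],
                       vx = vel[, 1], vy = vel[, 2], vz = vel[, 3],
                       ax = acc[, 1], ay = acc[, 2], az = acc[, 3]),
            class = c("mgs_kinematics", "data.frame"))
}

# Second-order central second derivative on a uniform grid, with 2nd-order
# one-sided stencils at the edges. Second order keeps the truncation error
# well above rounding noise at the package's default dt, so the O(dt^2)
# cross-validation against the analytic route is measurable.
central_second_derivative <- function(y, dt) {
  n <- length(y)
  d <- numeric(n)
  i <- 2:(n - 1)
  d[i] <- (y[i - 1] - 2 * y[i] + y[i + 1]) / dt^2
  d[1] <- (2 * y[1] - 5 * y[2] + 4 * y[3] - y[4]) / dt^2
  d[n] <- (2 * y[n] - 5 * y[n - 1] + 4 * y[n - 2] - y[n - 3]) / dt^2
  d
}

#' Apparent and gravity forces on a sample
#'
#' The apparent force is `F_a = m * a`, with `a` the kinematic acceleration of
#' the sample point due to machine motion; the gravity force is
#' `F_g = m * g` with the lab gravity vector `(0, 0, -9.80665)` m/s^2 and
#' `m = density * volume`. Other external forces (shear, magnetic) are of
#' minor influence at sample scale and are not modeled.
#'
#' @param sample An [sample_spec()] object.
#' @param a Acceleration: a numeric 3-vector, or an `n x 3` matrix for a time
#'   series (m/s^2).
#' @return A list with elements `F_a` and `F_g` (newtons), of the same shape
#'   as `a` (F_g is broadcast to a matrix when `a` is a matrix).
#' @export
apparent_and_gravity_force <- function(sample, a) {
  if (!inherits(sample, "mgs_sample_spec")) stop("bad 'sample'")
  g_vec <- lab_gravity_vector()
  if (is.matrix(a)) {
    if (ncol(a) != 3L) stop("'a' must have 3 columns")
    F_g <- matrix(sample$mass * g_vec, nrow(a), 3, byrow = TRUE)
  } else {
    if (length(a) != 3L) stop("'a' must be a 3-vector")
    F_g <- sample$mass * g_vec
  }
  list(F_a = sample$mass * a, F_g = F_g)
}

#' Running time-averaged gravity (residual gravity)
#'
#' The quality measure of gravity nullification: the running mean of the unit
#' gravity direction in the sample frame,
#' `gbar(T) = mean(u(t_k), t_k <= T)`, scaled by g. Its magnitude in units of
#' g equals the mean resultant length of the direction sample up to `T`; a
#' value decaying toward 0 indicates nullification, a plateau at `target_g`
#' indicates partial gravity.
#'
#' @param path An [direction_path()] object with uniform sampling.
#' @return An object of class `mgs_residual_series`: data frame with columns
#'   `t`, `gx, gy, gz` (running mean vector scaled by g, m/s^2) and
#'   `magnitude_g` (its norm in units of g, in `[0, 1]`; equals 1 at the
#'   first sample).
#' @export
residual_gravity <- function(path) {
  if (!inherits(path, "mgs_direction_path")) stop("residual_gravity: bad 'path'")
  u <- direction_matrix(path)
  n <- nrow(u)
  k <- seq_len(n)
  m <- cbind(cumsum(u[, 1]), cumsum(u[, 2]), cumsum(u[, 3])) / k
  structure(data.frame(t = path$t,
                       gx = g_std * m[, 1], gy = g_std * m[, 2],
                       gz = g_std * m[, 3],
                       magnitude_g = row_norms(m)),
            class = c("mgs_residual_series", "data.frame"))
}

#' @export
print.mgs_residual_series <- function(x, ...) {
  cat(sprintf("Residual gravity: %d samples, final |gbar| = %.4g g\n",
              nrow(x), x$magnitude_g[nrow(x)]))
  invisible(x)
}
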