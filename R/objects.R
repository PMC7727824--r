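#' Gimbal trajectory object
#'
#' A trajectory is the discrete realization of the machine's motion: a uniform
#' time series of the two gimbal angles together with their rates and
#' accelerations. It is stored as a data frame with columns
#' `t, alpha, beta, alpha_rate, beta_rate, alpha_acc, beta_acc` (SI units:
#' seconds, radians, rad/s, rad/s^2) plus the sampling interval `dt` as an
#' attribute.
#'
#' @param states Data frame with the seven columns above.
#' @param dt Sampling interval in seconds; must match the spacing of `t`.
#' @return An object of class `mgs_trajectory`.
#' @export
trajectory <- function(states, dt) {
  cols <- c("t", "alpha", "beta", "alpha_rate", "beta_rate",
            "alpha_acc", "beta_acc")
  if (!is.data.frame(states) || !all(cols %in% names(states)))
    stop("trajectory: 'states' must contain columns ",
         paste(cols, collapse = ", "))
  states <- states[cols]
  if (nrow(states) < 1L) stop("trajectory: empty state table")
  for (cl in cols) stopifnot_finite(states[[cl]], cl)
  if (!is.numeric(dt) || length(dt) != 1L || dt <= 0)
    stop("trajectory: 'dt' must be a positive scalar")
  if (nrow(states) > 1L) {
    steps <- diff(states$t)
    if (any(steps <= 0)) stop("trajectory: 't' must be strictly increasing")
    if (max(abs(steps - dt)) > 1e-9 * max(1, dt))
      stop("trajectory: non-uniform sampling (t spacing must equal dt)")
  }
  structure(states, dt = dt, class = c("mgs_trajectory", "data.frame"))
}

#' @export
print.mgs_trajectory <- function(x, ...) {
  cat(sprintf("Gimbal trajectory: %d states, dt = %g s, span %.6g s\n",
              nrow(x), attr(x, "dt"), x$t[nrow(x)] - x$t[1]))
  cat(sprintf("  alpha range [%.4g, %.4g] rad; beta range [%.4g, %.4g] rad\n",
              min(x$alpha), max(x$alpha), min(x$beta), max(x$beta)))
  invisible(x)
}

#' Gravity-direction path object
#'
#' The "path on the sphere": unit gravity-direction vectors in the sample
#' frame sampled over time. Stored as a data frame with columns
#' `t, ux, uy, uz`; every row has unit norm within 1e-9.
#'
#' @param t Numeric vector of timestamps in seconds.
#' @param u Numeric `n x 3` matrix of unit direction vectors.
#' @return An object of class `mgs_direction_path`.
#' @export
direction_path <- function(t, u) {
  u <- as.matrix(u)
  if (ncol(u) != 3L || nrow(u) != length(t))
    stop("direction_path: 'u' must be an n x 3 matrix matching length(t)")
  stopifnot_finite(u, "directions"); stopifnot_finite(t, "t")
  if (nrow(u) < 1L) stop("direction_path: empty path")
  if (max(abs(row_norms(u) - 1)) > 1e-9)
    stop("direction_path: directions must be unit vectors within 1e-9")
  structure(data.frame(t = t, ux = u[, 1], uy = u[, 2], uz = u[, 3]),
            class = c("mgs_direction_path", "data.frame"))
}

#' @export
print.mgs_direction_path <- function(x, ...) {
  cat(sprintf("Direction path: %d samples over %.6g s, mean resultant length %.4g\n",
              nrow(x), x$t[nrow(x)] - x$t[1],
              mean_resultant_length(direction_matrix(x))))
  invisible(x)
}

# n x 3 matrix of directions from a path object
direction_matrix <- function(path) {
  as.matrix(path[, c("ux", "uy", "uz")])
}

#' Sample (culture flask) specification
#'
#' Describes one mounted sample: its offset from the rotation center in
#' inner-frame coordinates, its control volume and density. The mass is
#' derived as `mass = density * volume`.
#'
#' @param offset Numeric 3-vector, m, position of the sample relative to the
#'   gimbal pivot, expressed in the inner (rotating) frame.
#' @param volume Control volume in m^3, strictly positive.
#' @param density Density in kg/m^3, strictly positive.
#' @return An object of class `mgs_sample_spec` with fields `offset`,
#'   `volume`, `density`, `mass`.
#' @examples
#' sample_spec(c(0, 0.1, 0), volume = 4e-15, density = 1000)
#' @export
sample_spec <- function(offset = c(0, 0, 0), volume = 1e-6, density = 1000) {
  if (length(offset) != 3L || !all(is.finite(offset)))
    stop("sample_spec: 'offset' must be a finite 3-vector")
  if (!is.finite(volume) || volume <= 0) stop("sample_spec: volume must be > 0")
  if (!is.finite(density) || density <= 0) stop("sample_spec: density must be > 0")
  structure(list(offset = as.numeric(offset), volume = volume,
                 density = density, mass = density * volume),
            class = "mgs_sample_spec")
}

#' @export
print.mgs_sample_spec <- function(x, ...) {
  cat(sprintf("Sample: offset (%g, %g, %g) m, V = %g m^3, rho = %g kg/m^3, m = %g kg\n",
              x$offset[1], x$offset[2], x$offset[3], x$volume, x$density, x$mass))
  invisible(x)
}

#' Gimbal motion limits
#'
#' Kinematic limits enforced by every planner: maximum angular rate,
#' acceleration and jerk per axis. Jerk limitation (bounding d(acc)/dt)
#' smooths reversals and velocity changes so that the machine introduces
#' minimal spurious shear and vibration.
#'
#' @param rate_max Maximum angular rate, rad/s.
#' @param acc_max Maximum angular acceleration, rad/s^2.
#' @param jerk_max Maximum angular jerk, rad/s^3.
#' @return An object of class `mgs_motion_limits`.
#' @details Defaults correspond to 60 deg/s, 60 deg/s^2 and 120 deg/s^3, a
#'   typical operating envelope for benchtop random positioning machines.
#' @export
motion_limits <- function(rate_max = pi / 3, acc_max = pi / 3,
                          jerk_max = 2 * pi / 3) {
  v <- c(rate_max, acc_max, jerk_max)
  if (!all(is.finite(v)) || any(v <= 0))
    stop("motion_limits: all limits must be strictly positive")
  structure(list(rate_max = rate_max, acc_max = acc_max, jerk_max = jerk_max),
            class = "mgs_motion_limits")
}

#' @export
print.mgs_motion_limits <- function(x, ...) {
  cat(sprintf("Motion limits: rate %.4g rad/s, acc %.4g rad/s^2, jerk %.4g rad/s^3\n",
              x$rate_max, x$acc_max, x$jerk_max))
  invisible(x)
}

#' Planner configuration
#'
#' Bundles everything a trajectory planner needs: run duration, sampling
#' interval, motion limits, gravity mode and seed.
#'
#' @param duration Total simulated time, s (> 0).
#' @param dt Sampling interval, s (> 0). Default 0.01 s.
#' @param limits An [motion_limits()] object.
#' @param mode `"zero"` for gravity nullification or `"partial"` for a
#'   controlled nonzero time-averaged gravity.
#' @param target_g Target residual gravity as a fraction of g (in `[0, 1)`);
#'   must be 0 in zero-gravity mode.
#' @param seed Integer seed making the planned trajectory reproducible, or
#'   `NULL` to use the current RNG stream.
#' @param compensation Logical; when `TRUE` the uniform-coverage planner
#'   orders waypoints greedily so the running time-average of the gravity
#'   direction is driven toward its target.
#' @return An object of class `mgs_planner_config`.
#' @export
planner_config <- function(duration, dt = 0.01, limits = motion_limits(),
                           mode = c("zero", "partial"), target_g = 0,
                           seed = NULL, compensation = TRUE) {
  mode <- match.arg(mode)
  if (!is.finite(duration) || duration <= 0) stop("planner_config: duration must be > 0")
  if (!is.finite(dt) || dt <= 0) stop("planner_config: dt must be > 0")
  if (!inherits(limits, "mgs_motion_limits")) stop("planner_config: bad 'limits'")
  if (!is.finite(target_g) || target_g < 0 || target_g >= 1)
    stop("planner_config: target_g must lie in [0, 1)")
  if (mode == "zero" && target_g != 0)
    stop("planner_config: target_g must be 0 in zero-gravity mode")
  structure(list(duration = duration, dt = dt, limits = limits, mode = mode,
                 target_g = target_g, seed = seed,
                 compensation = isTRUE(compensation)),
            class = "mgs_planner_config")
}

#' @export
print.mgs_planner_config <- function(x, ...) {
  cat(sprintf("Planner config: %s gravity%s, %g s at dt = %g s, seed %s, compensation %s\n",
              x$mode,
              if (x$mode == "partial") sprintf(" (target %.3g g)", x$target_g) else "",
              x$duration, x$dt,
              if (is.null(x$seed)) "none" else format(x$seed),
              if (x$compensation) "on" else "off"))
  invisible(x)
}
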