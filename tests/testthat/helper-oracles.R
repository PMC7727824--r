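# Independent oracles and fixture builders used across the test files.
# Everything here is deliberately naive (double loops, direct formulas) so it
# stays independent of the package's optimized code paths.

# Brute-force Ajne/Gine sums: plain double loop over unordered pairs.
oracle_gine <- function(U, normalization = "fn") {
  n <- nrow(U)
  st <- 0; ss <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    d <- sum(U[i, ] * U[j, ])
    d <- min(1, max(-1, d))
    st <- st + acos(d)
    ss <- ss + sin(acos(d))
  }
  ajne <- n / 4 - st / (n * pi)
  G <- n / 2 - 4 * ss / (n * pi)
  A <- if (normalization == "fn") 4 * ajne else 2 * ajne
  A + G
}

# Closed-form minimum time of a rest-to-rest seven-phase move, written from
# the textbook case analysis (independent of scurve_plan()).
oracle_scurve_time <- function(D, vmax, amax, jmax) {
  if (D <= 0) return(0)
  if (vmax * jmax >= amax^2) {          # acceleration can saturate
    va <- amax^2 / jmax                  # velocity gained in full jerk ramps
    da <- 2 * amax^3 / jmax^2            # distance of a full-jerk acc phase pair
    if (D * jmax^2 >= 2 * amax^3 && vmax >= va) {
      # does the move reach vmax with saturated acceleration?
      t_acc <- vmax / amax + amax / jmax       # time 0 -> vmax
      d_acc <- vmax * t_acc / 2
      if (D >= 2 * d_acc) return(2 * t_acc + (D - 2 * d_acc) / vmax)
    }
    # no cruise: peak velocity vp solves D = vp * (vp/amax + amax/jmax)
    vp <- (-amax^2 / jmax + sqrt(amax^4 / jmax^2 + 4 * amax * D)) / 2
    if (vp >= va) return(2 * (vp / amax + amax / jmax))
    # acceleration never saturates
    return(2 * (2 * (D / (2 * jmax))^(1 / 3)))
  }
  # rate saturates before acceleration can: jerk-limited ramps only
  tj <- sqrt(vmax / jmax)
  d_acc <- vmax * tj                     # distance while ramping 0 -> vmax
  if (D >= 2 * d_acc) return(4 * tj + (D - 2 * d_acc) / vmax)
  2 * 2 * (D / (2 * jmax))^(1 / 3)
}

# Smooth analytic gimbal trajectory on [0, span] for kinematics tests.
smooth_trajectory <- function(dt, span = 10) {
  t <- seq(0, round(span / dt)) * dt
  trajectory(data.frame(
    t = t,
    alpha = sin(0.7 * t), beta = 0.5 * cos(1.3 * t),
    alpha_rate = 0.7 * cos(0.7 * t), beta_rate = -0.65 * sin(1.3 * t),
    alpha_acc = -0.49 * sin(0.7 * t), beta_acc = -0.845 * cos(1.3 * t)),
    dt = dt)
}

# Constant-rate single-axis spin (2D clinostat limit).
spin_trajectory <- function(rate = 1, dt = 0.01, n = 1000) {
  t <- seq(0, n - 1) * dt
  trajectory(data.frame(
    t = t, alpha = rate * t, beta = 0,
    alpha_rate = rate, beta_rate = 0, alpha_acc = 0, beta_acc = 0), dt = dt)
}

# Exhaustive motion-limit scan of a trajectory; returns worst relative excess.
limit_excess <- function(traj, limits) {
  dt <- attr(traj, "dt")
  max(max(abs(traj$alpha_rate), abs(traj$beta_rate)) / limits$rate_max,
      max(abs(traj$alpha_acc), abs(traj$beta_acc)) / limits$acc_max,
      max(abs(diff(traj$alpha_acc)), abs(diff(traj$beta_acc))) / dt /
        limits$jerk_max)
}
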