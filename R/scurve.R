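# Jerk-limited (S-curve) motion profiles.
#
# A rest-to-rest move under rate/acceleration/jerk limits follows the classic
# seven-phase profile: jerk+, acc hold, jerk-, cruise, jerk-, acc hold, jerk+.
# Short moves degenerate by dropping the cruise and/or the acc-hold phases.

# Phase-plan for a rest-to-rest move of distance D >= 0.
# Returns list(t_j, t_a, t_v, v_pk, a_pk); total time = 4 t_j + 2 t_a + t_v.
scurve_plan <- function(D, limits) {
  j <- limits$jerk_max; amax <- limits$acc_max; vmax <- limits$rate_max
  if (D <= 0) return(list(t_j = 0, t_a = 0, t_v = 0, v_pk = 0, a_pk = 0))
  # acceleration ramp shape needed to reach vmax
  if (vmax < amax^2 / j) {             # vmax reached before acc saturates
    t_j <- sqrt(vmax / j); t_a <- 0
  } else {
    t_j <- amax / j; t_a <- vmax / amax - t_j
  }
  d_ramps <- vmax * (2 * t_j + t_a)    # distance of accel + decel ramps
  if (D >= d_ramps) {
    return(list(t_j = t_j, t_a = t_a, t_v = (D - d_ramps) / vmax,
                v_pk = vmax, a_pk = j * t_j))
  }
  # no cruise; try acc-saturated triangle-ish profile
  t_j <- amax / j
  v_pk <- (-amax * t_j + sqrt((amax * t_j)^2 + 4 * amax * D)) / 2
  t_a <- v_pk / amax - t_j
  if (t_a >= 0) return(list(t_j = t_j, t_a = t_a, t_v = 0,
                            v_pk = v_pk, a_pk = amax))
  # fully triangular acceleration (acc never saturates)
  t_j <- (D / (2 * j))^(1 / 3)
  list(t_j = t_j, t_a = 0, t_v = 0, v_pk = j * t_j^2, a_pk = j * t_j)
}

# Minimum rest-to-rest move time for distance D (vectorized over D).
scurve_duration <- function(D, limits) {
  vapply(D, function(d) {
    p <- scurve_plan(abs(d), limits)
    4 * p$t_j + 2 * p$t_a + p$t_v
  }, numeric(1))
}

# Seven-phase profile table for a move from q0 to q1, optionally stretched in
# time to `T_target` >= the minimum move time. Stretching phase durations by s
# and jerks by 1/s^3 slows the move while keeping rate/acc/jerk within (below)
# the limits, which is how the planner synchronizes the two axes of a segment.
scurve_phases <- function(q0, q1, limits, T_target = NULL) {
  D <- abs(q1 - q0); s <- sign(q1 - q0)
  p <- scurve_plan(D, limits)
  total <- 4 * p$t_j + 2 * p$t_a + p$t_v
  j <- limits$jerk_max * s
  dur <- c(p$t_j, p$t_a, p$t_j, p$t_v, p$t_j, p$t_a, p$t_j)
  jerk <- c(j, 0, -j, 0, -j, 0, j)
  if (!is.null(T_target) && total > 0 && T_target > total) {
    sc <- T_target / total
    dur <- dur * sc
    jerk <- jerk / sc^3
    total <- T_target
  }
  keep <- dur > 0
  list(phases = data.frame(dur = dur[keep], jerk = jerk[keep]), total = total)
}

#' Jerk-limited point-to-point gimbal move
#'
#' Plans a rest-to-rest move of one gimbal axis from `q0` to `q1` as a
#' seven-phase jerk-limited (S-curve) profile and samples it on a uniform
#' grid. Smoothed reversals of this kind keep spurious shear forces and
#' structural vibration to a minimum.
#'
#' @param q0,q1 Start and end angles, rad.
#' @param limits An [motion_limits()] object.
#' @param dt Sampling interval, s.
#' @param T_target Optional move duration, s. When longer than the minimum
#'   move time the profile is stretched uniformly (still jerk-limited, with
#'   proportionally lower peaks); used to synchronize the two gimbal axes.
#' @return A data frame with columns `t, q, qd, qdd` sampled at `dt` from 0 up
#'   to the first grid point at or beyond the minimum move time (the endpoint
#'   state `q1`, rate 0, acceleration 0 is exact there). A null move
#'   (`q0 == q1`) returns a single-sample constant profile.
#' @export
scurve_segment <- function(q0, q1, limits, dt, T_target = NULL) {
  if (!inherits(limits, "mgs_motion_limits")) stop("scurve_segment: bad 'limits'")
  if (!is.finite(dt) || dt <= 0) stop("scurve_segment: dt must be > 0")
  if (!is.finite(q0) || !is.finite(q1)) stop("scurve_segment: angles must be finite")
  if (q0 == q1)
    return(data.frame(t = 0, q = q0, qd = 0, qdd = 0))
  pp <- scurve_phases(q0, q1, limits, T_target)
  n <- ceiling(pp$total / dt - 1e-9)
  t <- seq(0, n) * dt
  prof <- eval_phase_chain(t, q0, 0, 0, pp$phases)
  done <- t >= pp$total - 1e-12
  prof$q[done] <- q1; prof$qd[done] <- 0; prof$qdd[done] <- 0
  data.frame(t = t, q = prof$q, qd = prof$qd, qdd = prof$qdd)
}

# Jerk-limited change of angular rate from v0 to v1 (no position target),
# used by the conventional random controller between dwell periods.
# Returns phases data.frame(dur, jerk); duration 0 when v0 == v1.
rate_ramp_phases <- function(v0, v1, limits) {
  dv <- abs(v1 - v0); s <- sign(v1 - v0)
  if (dv == 0) return(data.frame(dur = numeric(0), jerk = numeric(0)))
  j <- limits$jerk_max
  a_pk <- min(limits$acc_max, sqrt(j * dv))
  t_j <- a_pk / j
  t_c <- (dv - a_pk * t_j) / a_pk
  data.frame(dur = c(t_j, t_c, t_j)[c(TRUE, t_c > 0, TRUE)],
             jerk = c(j * s, 0, -j * s)[c(TRUE, t_c > 0, TRUE)])
}
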