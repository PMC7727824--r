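# Trajectory planners: the three control schemes of a two-axis microgravity
# simulator. All planners respect the configured motion limits at every
# sample and are bit-reproducible for a fixed seed.

#' Random walk on the sphere
#'
#' The idealized description of conventional random positioning: the gravity
#' direction performs geodesic steps of fixed arc length on the unit sphere,
#' turning exactly 90 degrees left or right (probability 1/2 each) after
#' every step. After enough steps the visited points cover the sphere
#' homogeneously.
#'
#' @param n_steps Number of steps (>= 1). Default 10000.
#' @param step_arc Arc length of one geodesic step, rad, in (0, pi).
#'   Default 5 degrees.
#' @param seed Optional integer seed for reproducibility.
#' @return An [direction_path()] with `n_steps + 1` points (the start point
#'   `(0, 0, -1)` included); timestamps are the step indices in seconds.
#' @export
random_walk_sphere <- function(n_steps = 10000, step_arc = 5 * pi / 180,
                               seed = NULL) {
  if (!is.finite(n_steps) || n_steps < 1) stop("random_walk_sphere: n_steps >= 1")
  if (!is.finite(step_arc) || step_arc <= 0 || step_arc >= pi)
    stop("random_walk_sphere: step_arc must lie in (0, pi)")
  with_seed(seed, {
    turns <- sample(c(-1, 1), n_steps, replace = TRUE)
    p <- c(0, 0, -1); h <- c(1, 0, 0)
    U <- matrix(0, n_steps + 1L, 3); U[1, ] <- p
    ca <- cos(step_arc); sa <- sin(step_arc)
    for (k in seq_len(n_steps)) {
      p_new <- ca * p + sa * h
      h_new <- -sa * p + ca * h        # heading parallel-transported along step
      p <- p_new / vec_norm(p_new)
      # 90 degree turn about the surface normal: h -> +/- (p x h)
      h <- turns[k] * c(p[2] * h_new[3] - p[3] * h_new[2],
                        p[3] * h_new[1] - p[1] * h_new[3],
                        p[1] * h_new[2] - p[2] * h_new[1])
      h <- h / vec_norm(h)
      U[k + 1L, ] <- p
    }
    direction_path(0:n_steps, U)
  })
}

# Evaluate a chain of constant-jerk phases on a sorted time grid, fast path:
# per-phase start states are accumulated once, then each sample is evaluated
# from its phase start in vectorized arithmetic.
eval_phase_chain <- function(t, q0, v0, a0, phases) {
  np <- nrow(phases)
  starts <- cumsum(c(0, phases$dur))
  q <- numeric(np + 1L); v <- numeric(np + 1L); a <- numeric(np + 1L)
  q[1] <- q0; v[1] <- v0; a[1] <- a0
  if (np > 0) for (k in seq_len(np)) {
    d <- phases$dur[k]; jk <- phases$jerk[k]
    q[k + 1L] <- q[k] + v[k] * d + a[k] * d^2 / 2 + jk * d^3 / 6
    v[k + 1L] <- v[k] + a[k] * d + jk * d^2 / 2
    a[k + 1L] <- a[k] + jk * d
  }
  idx <- findInterval(t, starts, rightmost.closed = FALSE)
  idx[idx < 1L] <- 1L
  jerk_of <- c(phases$jerk, 0)
  tau <- t - starts[idx]
  jk <- jerk_of[idx]
  list(q  = q[idx] + v[idx] * tau + a[idx] * tau^2 / 2 + jk * tau^3 / 6,
       qd = v[idx] + a[idx] * tau + jk * tau^2 / 2,
       qdd = a[idx] + jk * tau)
}

#' Conventional random axis control
#'
#' Emulates the classic random positioning scheme: each axis independently
#' holds a random constant rate (uniform in `[-rate_max, rate_max]`) for a
#' random dwell time (uniform in 1 to 10 s) and then ramps, jerk-limited, to
#' the next random rate. Randomly controlled rotation of this kind does not
#' produce a homogeneous path distribution: the induced gravity-direction
#' path concentrates at the poles of the inner gimbal axis.
#'
#' @param config An [planner_config()] object (`mode` is ignored; the scheme
#'   has no gravity target).
#' @param dwell_range Length-2 numeric, the dwell-time range in seconds.
#' @return An [trajectory()] spanning `config$duration` with
#'   `duration/dt + 1` states.
#' @export
classic_random_control <- function(config, dwell_range = c(1, 10)) {
  if (!inherits(config, "mgs_planner_config")) stop("classic_random_control: bad config")
  lim <- config$limits
  with_seed(config$seed, {
    axis_chain <- function() {
      phases <- list(); tot <- 0; v <- 0
      while (tot < config$duration) {
        v_new <- runif(1, -lim$rate_max, lim$rate_max)
        ramp <- rate_ramp_phases(v, v_new, lim)
        dwell <- data.frame(dur = runif(1, dwell_range[1], dwell_range[2]),
                            jerk = 0)
        phases[[length(phases) + 1L]] <- rbind(ramp, dwell)
        tot <- tot + sum(ramp$dur) + dwell$dur
        v <- v_new
      }
      do.call(rbind, phases)
    }
    n <- round(config$duration / config$dt)
    t <- seq(0, n) * config$dt
    A <- eval_phase_chain(t, 0, 0, 0, axis_chain())
    B <- eval_phase_chain(t, 0, 0, 0, axis_chain())
    trajectory(data.frame(t = t, alpha = A$q, beta = B$q,
                          alpha_rate = A$qd, beta_rate = B$qd,
                          alpha_acc = A$qdd, beta_acc = B$qdd),
               dt = config$dt)
  })
}

# Deterministic low-discrepancy point set: spherical Fibonacci lattice.
fibonacci_sphere <- function(m) {
  i <- seq_len(m) - 0.5
  phi <- pi * (1 + sqrt(5)) * i
  z <- 1 - 2 * i / m
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(r * cos(phi), r * sin(phi), z)
}

#' Optimized uniform-coverage trajectory planner
#'
#' Plans the machine's motion so that the gravity direction in the sample
#' frame visits a set of waypoint directions connected by jerk-limited
#' rest-to-rest gimbal moves. In zero-gravity mode the waypoints are a
#' low-discrepancy spherical Fibonacci set; in partial-gravity mode they are
#' drawn from a von Mises-Fisher distribution about `-z` whose mean resultant
#' length equals `target_g`. With `compensation = TRUE` the visiting order is
#' chosen greedily so the running time-average of the gravity direction is
#' driven toward the target mean vector (`0` in zero mode,
#' `(0, 0, -target_g)` in partial mode), which is what makes the residual
#' gravity decay toward the target instead of wandering at the Monte-Carlo
#' rate.
#'
#' @param config An [planner_config()] object.
#' @return An [trajectory()] with exactly `duration/dt + 1` states.
#' @export
uniform_coverage_planner <- function(config) {
  if (!inherits(config, "mgs_planner_config")) stop("uniform_coverage_planner: bad config")
  lim <- config$limits; dt <- config$dt
  t_ref <- scurve_duration(1.5, lim)     # typical inter-waypoint gimbal move
  if (scurve_duration(pi, lim) > config$duration)
    stop("uniform_coverage_planner: infeasible limits - a single waypoint move ",
         "does not fit within the requested duration")
  M <- max(8L, as.integer(ceiling(config$duration / t_ref)))
  with_seed(config$seed, {
    if (config$mode == "zero") {
      # seeded random rotation of the lattice varies the run while keeping
      # its low-discrepancy coverage
      W <- fibonacci_sphere(M) %*% random_rotation_matrix()
      target_vec <- c(0, 0, 0)
    } else {
      kappa <- vmf_concentration(config$target_g)
      W <- sample_vmf(n = M, mu = c(0, 0, -1), kappa = kappa)
      target_vec <- c(0, 0, -config$target_g)
    }
    # move-time lookup by gimbal distance, for greedy contribution estimates
    th_grid <- seq(0, pi, length.out = 64)
    dur_grid <- scurve_duration(th_grid, lim)
    # vectorized inverse kinematics: per-candidate max-axis gimbal distance
    # from `pose` (nearest branch, matching inverse_kinematics())
    gimbal_dist <- function(Wc, pose) {
      a1 <- asin(pmin(1, pmax(-1, -Wc[, 2])))
      b1 <- atan2(Wc[, 1], -Wc[, 3])
      d_branch <- function(a, b) {
        au <- a + 2 * pi * round((pose[1] - a) / (2 * pi))
        bu <- b + 2 * pi * round((pose[2] - b) / (2 * pi))
        cbind(abs(au - pose[1]), abs(bu - pose[2]))
      }
      d1 <- d_branch(a1, b1); d2 <- d_branch(pi - a1, b1 + pi)
      use1 <- d1[, 1]^2 + d1[, 2]^2 <= d2[, 1]^2 + d2[, 2]^2
      ifelse(use1, pmax(d1[, 1], d1[, 2]), pmax(d2[, 1], d2[, 2]))
    }

    # Coverage accounting (zero mode): the gimbal over-dwells near its poles
    # (+/- y, where azimuthal sphere speed is limited by cos(alpha)), so the
    # greedy choice balances the running mean AND steers waypoints toward
    # currently under-covered equal-area cells. Cells are latitude rings
    # about the gimbal pole axis.
    covering <- config$compensation && config$mode == "zero"
    if (covering) {
      cov_rings <- 8L
      cov_m <- pmax(1L, as.integer(round(
        2 * cov_rings * sin(pi * (seq_len(cov_rings) - 0.5) / cov_rings))))
      cov_zb <- -1 + 2 * cumsum(c(0, cov_m)) / sum(cov_m)
      cov_zb[length(cov_zb)] <- 1
      cov_cell <- function(U) {
        ring <- findInterval(U[, 2], cov_zb, rightmost.closed = TRUE)
        ring[ring < 1L] <- 1L; ring[ring > cov_rings] <- cov_rings
        phi <- atan2(U[, 1], U[, 3])
        off <- cumsum(c(0L, cov_m))[ring]
        off + pmin(cov_m[ring], 1L + as.integer(floor((phi + pi) / (2 * pi) * cov_m[ring])))
      }
      cov_counts <- numeric(sum(cov_m))
      W_cell <- cov_cell(W)
    }

    n_total <- round(config$duration / dt) + 1L
    alpha <- numeric(n_total); beta <- numeric(n_total)
    arate <- numeric(n_total); brate <- numeric(n_total)
    aacc <- numeric(n_total); bacc <- numeric(n_total)
    filled <- 1L                          # row 1 is the rest pose (0, 0)
    pose <- c(0, 0)
    u_cur <- gravity_direction(pose[1], pose[2])
    S <- u_cur * dt                       # integral of u dt over emitted rows
    t_cur <- dt
    remaining <- rep(TRUE, M)
    while (filled < n_total) {
      # refresh the pool before it thins out to the leftovers, which would
      # leave the greedy only poorly placed candidates
      if (sum(remaining) < max(8L, M %/% 4L)) remaining <- rep(TRUE, M)
      idx <- which(remaining)
      if (config$compensation) {
        Wc <- W[idx, , drop = FALSE]
        t_est <- stats::approx(th_grid, dur_grid, gimbal_dist(Wc, pose),
                               rule = 2)$y
        contrib <- (Wc + rep(u_cur, each = length(idx))) * 0.5 * t_est
        miss <- contrib + rep(S, each = length(idx)) -
          (t_cur + t_est) %*% t(target_vec)
        miss2 <- rowSums(miss^2)
        on_track <- min(sqrt(miss2)) < 2 * t_ref
        if (covering && on_track && length(idx) > 1L) {
          # among candidates whose compensation miss is within half a typical
          # segment contribution of the best, take the waypoint whose cell is
          # most under-covered so far: coverage is balanced without letting
          # the running mean drift by more than O(one segment)
          short <- which(sqrt(miss2) <= min(sqrt(miss2)) + 0.5 * t_ref)
          k <- idx[short[which.min(cov_counts[W_cell[idx[short]]])]]
        } else {
          k <- idx[which.min(miss2)]
        }
      } else {
        k <- idx[1L]
      }
      remaining[k] <- FALSE
      tgt <- inverse_kinematics(W[k, ], current = pose)
      # synchronize the axes: stretch the quicker move to the common (grid-
      # aligned) duration so both axes are in motion for the whole segment
      T_seg <- max(scurve_duration(abs(tgt - pose), lim))
      T_seg <- max(1L, ceiling(T_seg / dt - 1e-9)) * dt
      pa <- scurve_segment(pose[1], tgt[1], lim, dt, T_target = T_seg)
      pb <- scurve_segment(pose[2], tgt[2], lim, dt, T_target = T_seg)
      ns <- max(nrow(pa), nrow(pb), 2L)
      pad <- function(p, ns) {
        extra <- ns - nrow(p)
        if (extra > 0) {
          hold <- p[rep(nrow(p), extra), ]
          hold$qd <- 0; hold$qdd <- 0
          p <- rbind(p, hold)
        }
        p[-1L, , drop = FALSE]            # drop t=0 row shared with previous
      }
      pa <- pad(pa, ns); pb <- pad(pb, ns)
      take <- min(nrow(pa), n_total - filled)
      rows <- filled + seq_len(take)
      alpha[rows] <- pa$q[1:take]; beta[rows] <- pb$q[1:take]
      arate[rows] <- pa$qd[1:take]; brate[rows] <- pb$qd[1:take]
      aacc[rows] <- pa$qdd[1:take]; bacc[rows] <- pb$qdd[1:take]
      useg <- gravity_direction(alpha[rows], beta[rows])
      if (take == 1L) useg <- matrix(useg, 1L, 3L)
      S <- S + colSums(useg) * dt
      if (covering) {
        tb <- tabulate(cov_cell(useg), nbins = length(cov_counts))
        cov_counts <- cov_counts + tb
      }
      t_cur <- t_cur + take * dt
      filled <- filled + take
      pose <- tgt
      u_cur <- gravity_direction(pose[1], pose[2])
    }
    t <- seq(0, n_total - 1L) * dt
    trajectory(data.frame(t = t, alpha = alpha, beta = beta,
                          alpha_rate = arate, beta_rate = brate,
                          alpha_acc = aacc, beta_acc = bacc),
               dt = dt)
  })
}

#' Gravity-direction path of a trajectory
#'
#' Applies [gravity_direction()] to every `decimate`-th state of a
#' trajectory. Decimation thins the serially correlated path before
#' uniformity testing (the spherical-uniformity statistics assume
#' approximately independent samples).
#'
#' @param traj An [trajectory()] object.
#' @param decimate Keep every `decimate`-th state (>= 1). Default 1.
#' @return An [direction_path()] with `ceiling(n/decimate)` points and the
#'   original timestamps.
#' @export
trajectory_to_direction_path <- function(traj, decimate = 1L) {
  if (!inherits(traj, "mgs_trajectory")) stop("bad 'traj'")
  decimate <- as.integer(decimate)
  if (is.na(decimate) || decimate < 1L) stop("'decimate' must be >= 1")
  idx <- seq(1L, nrow(traj), by = decimate)
  u <- gravity_direction(traj$alpha[idx], traj$beta[idx])
  if (length(idx) == 1L) u <- matrix(u, 1L, 3L)
  direction_path(traj$t[idx], u)
}
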