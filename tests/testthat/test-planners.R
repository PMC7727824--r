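test_that("random walk on the sphere takes fixed 90-degree-turn geodesic steps", {
  p <- random_walk_sphere(500, step_arc = 5 * pi / 180, seed = 31)
  U <- as.matrix(p[, c("ux", "uy", "uz")])
  expect_lt(max(abs(sqrt(rowSums(U^2)) - 1)), 1e-9)
  dots <- rowSums(U[-nrow(U), ] * U[-1, ])
  expect_lt(max(abs(dots - cos(5 * pi / 180))), 1e-9)
  # step-by-step oracle for the first two steps, using the drawn turn signs
  set.seed(31)
  turns <- sample(c(-1, 1), 2, replace = TRUE)
  arc <- 5 * pi / 180
  p0 <- c(0, 0, -1); h0 <- c(1, 0, 0)
  p1 <- cos(arc) * p0 + sin(arc) * h0
  xp <- function(a, b) c(a[2] * b[3] - a[3] * b[2],
                         a[3] * b[1] - a[1] * b[3],
                         a[1] * b[2] - a[2] * b[1])
  h1 <- turns[1] * xp(p1, -sin(arc) * p0 + cos(arc) * h0)
  p2 <- cos(arc) * p1 + sin(arc) * h1
  expect_equal(unname(U[2, ]), p1, tolerance = 1e-12)
  expect_equal(unname(U[3, ]), p2, tolerance = 1e-9)
  # reproducible under a fixed seed
  expect_identical(random_walk_sphere(50, seed = 31),
                   random_walk_sphere(50, seed = 31))
  expect_error(random_walk_sphere(10, step_arc = 4), "step_arc")
})

test_that("conventional random control respects limits and concentrates at the gimbal poles", {
  cfg <- planner_config(2000, dt = 0.05, seed = 12)
  traj <- classic_random_control(cfg)
  expect_equal(nrow(traj), 2000 / 0.05 + 1)
  expect_lte(limit_excess(traj, cfg$limits), 1 + 1e-9)
  # polar caps of the inner-axis poles hold at least twice the uniform share
  u <- trajectory_to_direction_path(traj)
  cap <- mean(abs(u$uy) > 0.9)
  expect_gte(cap, 2 * 0.1)
  # uniformity factor far above the uniform reference on a dense path
  f <- gine_F(trajectory_to_direction_path(classic_random_control(
    planner_config(100, dt = 0.01, seed = 7))))
  expect_gt(f$F_star, 3.633 * 10)
})

test_that("inverse kinematics round-trips and resolves gimbal lock", {
  expect_equal(inverse_kinematics(c(0, 0, -1)), c(0, 0))
  ab <- inverse_kinematics(c(0, 0, 1))
  expect_equal(gravity_direction(ab[1], ab[2]), c(0, 0, 1), tolerance = 1e-9)
  set.seed(14)
  U <- sample_uniform_sphere(1000)
  cur <- c(0, 0)
  for (k in seq_len(nrow(U))) {
    ab <- inverse_kinematics(U[k, ], current = cur)
    expect_lt(max(abs(gravity_direction(ab[1], ab[2]) - U[k, ])), 1e-6)
    cur <- ab
  }
  # at gimbal lock the redundant inner angle keeps its current value
  lock <- inverse_kinematics(c(0, -1, 0), current = c(0.1, 2.5))
  expect_equal(lock[2], 2.5)
  expect_equal(gravity_direction(lock[1], lock[2]), c(0, -1, 0),
               tolerance = 1e-9)
  expect_error(inverse_kinematics(c(0, 0, -2)), "unit")
})

test_that("the uniform-coverage planner respects limits, row counts and seeding", {
  cfg <- planner_config(120, dt = 0.01, seed = 4)
  traj <- uniform_coverage_planner(cfg)
  expect_equal(nrow(traj), 120 / 0.01 + 1)
  expect_lte(limit_excess(traj, cfg$limits), 1 + 1e-9)
  # stored rates agree with finite differences of the angles
  n <- nrow(traj)
  fd <- (traj$alpha[3:n] - traj$alpha[1:(n - 2)]) / (2 * 0.01)
  expect_lt(max(abs(fd - traj$alpha_rate[2:(n - 1)])), 1e-3)
  expect_identical(uniform_coverage_planner(cfg), traj)
  expect_error(uniform_coverage_planner(
    planner_config(1, dt = 0.01, seed = 1)), "infeasible")
})

test_that("zero-gravity runs pass the uniformity test in over 90% of seeds", {
  cal <- calibrate_null(600, 200, seed = 81)
  crit <- cal$percentiles[["95%"]]
  pass <- vapply(1:10, function(seed) {
    traj <- uniform_coverage_planner(planner_config(360, dt = 0.01, seed = seed))
    dec <- trajectory_to_direction_path(traj, decimate = 60)
    gine_F(dec)$F_star < crit
  }, logical(1))
  expect_gte(mean(pass), 0.9)
})

test_that("greedy compensation keeps the running direction integral bounded", {
  traj <- uniform_coverage_planner(planner_config(600, dt = 0.01, seed = 6))
  rg <- residual_gravity(trajectory_to_direction_path(traj))
  idx <- round(seq(60, 600, by = 60) / 0.01) + 1L
  # |integral of u dt| = magnitude * elapsed stays of the order of one
  # segment contribution, giving the ~1/T decay envelope
  expect_lt(max(rg$magnitude_g[idx] * rg$t[idx]), 8)
  expect_lt(rg$magnitude_g[idx[10]], 0.25 * rg$magnitude_g[round(30 / 0.01) + 1L])
})

test_that("partial-gravity runs recover the target mean resultant length", {
  for (tg in c(0.1, 0.2, 0.4, 0.8)) {
    traj <- uniform_coverage_planner(planner_config(
      2000, dt = 0.05, mode = "partial", target_g = tg, seed = 11))
    mrl <- mean_resultant_length(trajectory_to_direction_path(traj))
    expect_lt(abs(mrl - tg) / tg, 0.05)
  }
})

test_that("direction-path extraction decimates and preserves geometry", {
  traj <- spin_trajectory(rate = 0.5, dt = 0.01, n = 1000)
  expect_equal(nrow(trajectory_to_direction_path(traj, 1)), 1000)
  expect_equal(nrow(trajectory_to_direction_path(traj, 10)), 100)
  expect_equal(nrow(trajectory_to_direction_path(traj, 7)), ceiling(1000 / 7))
  # single-axis spin traces a great circle: all directions orthogonal to the
  # body image of the spin axis (outer axis = x of the body at beta = 0)
  u <- trajectory_to_direction_path(traj, 10)
  expect_lt(max(abs(u$ux)), 1e-12)
})

test_that("samples mounted symmetrically are treated identically", {
  traj <- uniform_coverage_planner(planner_config(60, dt = 0.01, seed = 2))
  rep <- equality_report(traj, list(sample_spec(c(0, 0.08, 0)),
                                    sample_spec(c(0, -0.08, 0)),
                                    sample_spec(c(0, 0.16, 0)),
                                    sample_spec(c(0, 0, 0))))
  expect_equal(nrow(rep), 4)
  expect_lt(abs(rep$rms_acc[1] - rep$rms_acc[2]) / rep$rms_acc[1], 1e-9)
  expect_equal(rep$rms_acc[3] / rep$rms_acc[1], 2, tolerance = 1e-6)
  expect_equal(rep$rms_acc[4], 0)
})
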