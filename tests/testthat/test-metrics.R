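test_that("uniformity components match hand-computed two-point values", {
  antipodal <- rbind(c(0, 0, 1), c(0, 0, -1))
  coincident <- rbind(c(1, 0, 0), c(1, 0, 0))
  # theta = pi: Ajne component 0, Gine component 1 under either normalization
  for (norm in c("fn", "sum")) {
    r <- gine_F(antipodal, normalization = norm)
    expect_equal(r$A_n, 0)
    expect_equal(r$G_n, 1)
    expect_equal(r$F_star, 1)
    expect_equal(r$F_star, r$A_n + r$G_n)
  }
  # theta = 0: raw Ajne = 1/2; weighted 2 (classical) or 1 (plain sum)
  r <- gine_F(coincident, normalization = "sum")
  expect_equal(r$A_n, 1)
  expect_equal(r$G_n, 1)
  expect_equal(r$F_star, 2)
  r <- gine_F(coincident, normalization = "fn")
  expect_equal(r$A_n, 2)
  expect_equal(r$F_star, 3)
  expect_error(gine_F(rbind(c(1, 0, 0))), "2 points")
  expect_error(gine_F(rbind(c(1, 0, 0), c(2, 0, 0))), "unit")
})

test_that("gine_F equals the brute-force double loop on random sets", {
  set.seed(33)
  for (n in c(5, 17, 50)) {
    U <- sample_uniform_sphere(n)
    for (norm in c("fn", "sum"))
      expect_equal(gine_F(U, norm)$F_star, oracle_gine(U, norm),
                   tolerance = 1e-10)
  }
})

test_that("the uniformity factor is rotation invariant", {
  set.seed(44)
  U <- sample_uniform_sphere(80)
  for (k in 1:5) {
    q <- rnorm(4); q <- q / sqrt(sum(q^2))      # random rotation, quaternion
    w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
    R <- matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
                  2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
                  2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
                3, 3, byrow = TRUE)
    expect_equal(gine_F(U %*% t(R))$F_star, gine_F(U)$F_star, tolerance = 1e-9)
  }
})

test_that("the uniformity factor grows with von Mises-Fisher concentration", {
  f <- vapply(c(0, 1, 5, 20, 100), function(kappa) {
    mean(vapply(1:5, function(s)
      gine_F(sample_vmf(150, kappa = kappa, seed = 100 + 7 * s + round(kappa)))$F_star,
      numeric(1)))
  }, numeric(1))
  expect_true(all(diff(f) > 0))
})

test_that("null calibration is deterministic, monotone, and stable in n", {
  c1 <- calibrate_null(100, 200, seed = 5)
  c2 <- calibrate_null(100, 200, seed = 5)
  expect_identical(c1$percentiles, c2$percentiles)
  expect_true(all(diff(c1$percentiles) > 0))
  expect_error(calibrate_null(5, 200), "n >= 10")
  expect_error(calibrate_null(100, 50), "reps >= 100")
  # the null distribution is essentially independent of n for large n
  cA <- calibrate_null(100, 1500, seed = 6)
  cB <- calibrate_null(400, 1500, seed = 7)
  se <- sd(cA$values) / sqrt(1500)
  expect_lt(abs(cA$mean - cB$mean), 6 * se)
  expect_lt(abs(cA$percentiles[["95%"]] - cB$percentiles[["95%"]]), 0.25)
})

test_that("percentile estimates converge as replicates grow", {
  cS <- calibrate_null(60, 400, seed = 8)
  cL <- calibrate_null(60, 4000, seed = 9)
  # bootstrap the small calibration's 95th percentile
  set.seed(10)
  boot <- replicate(300, quantile(sample(cS$values, replace = TRUE), 0.95))
  ci <- quantile(boot, c(0.005, 0.995))
  expect_gte(cL$percentiles[["95%"]], ci[[1]] - 0.05)
  expect_lte(cL$percentiles[["95%"]], ci[[2]] + 0.05)
})

test_that("equal-area sphere histogram has exactly equal cells and flags clumping", {
  h <- sphere_histogram(sample_uniform_sphere(1000, seed = 3), n_rings = 12)
  areas <- with(h$cells, (z_hi - z_lo) * 2 * pi /
                  tabulate(ring)[ring])
  expect_lt(diff(range(areas)) / mean(areas), 1e-12)
  expect_equal(sum(h$cells$count), 1000)
  expect_equal(nrow(h$cells) * h$cell_area, 4 * pi, tolerance = 1e-12)
  # all mass at the north pole occupies a single cell
  pole <- matrix(rep(c(0, 0, 1), each = 40), 40)
  hp <- sphere_histogram(pole, n_rings = 6)
  expect_equal(sum(hp$cells$count > 0), 1L)
  expect_equal(hp$density_ratio, Inf)
  # iid uniform counts stay within 5 sd of the common mean (multinomial)
  big <- sphere_histogram(sample_uniform_sphere(20000, seed = 4), n_rings = 8)
  m <- 20000 / nrow(big$cells)
  sd_m <- sqrt(m * (1 - 1 / nrow(big$cells)))
  expect_true(all(abs(big$cells$count - m) <= 5 * sd_m))
})

test_that("direction samplers have the advertised first moments", {
  U <- sample_uniform_sphere(4000, seed = 21)
  expect_lte(mean_resultant_length(U), 3 / sqrt(4000))
  expect_lt(max(abs(sqrt(rowSums(U^2)) - 1)), 1e-12)
  # kappa = 0 reduces to uniform: passes the uniformity test
  cal <- calibrate_null(200, 300, seed = 22)
  expect_lt(gine_F(sample_vmf(200, kappa = 0, seed = 23))$F_star,
            cal$percentiles[["95%"]])
  # strong concentration drives the mean resultant length to 1
  expect_gt(mean_resultant_length(sample_vmf(2000, kappa = 300, seed = 24)),
            0.99)
  # mean direction of a concentrated sample is mu
  V <- sample_vmf(3000, mu = c(0, -1, 0), kappa = 50, seed = 25)
  expect_lt(sum(colMeans(V) * c(0, -1, 0)) / mean_resultant_length(V) - 1, 1e-6)
})

test_that("vmf_concentration inverts the mean resultant length", {
  for (rho in c(0.05, 0.1, 0.4, 0.8, 0.95)) {
    k <- vmf_concentration(rho)
    expect_equal(1 / tanh(k) - 1 / k, rho, tolerance = 1e-9)
  }
  expect_equal(vmf_concentration(0), 0)
  # empirical check at one value
  mrl <- mean_resultant_length(sample_vmf(20000, kappa = vmf_concentration(0.4),
                                          seed = 26))
  expect_equal(mrl, 0.4, tolerance = 0.02)
})
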