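# Direction samplers used for calibration and for partial-gravity waypoint
# pools, plus small directional summaries.

#' Uniform directions on the sphere
#'
#' Samples iid uniform unit vectors by normalizing standard trivariate
#' Gaussians.
#'
#' @param n Number of directions (>= 1).
#' @param seed Optional integer seed.
#' @return An `n x 3` matrix of unit rows.
#' @export
sample_uniform_sphere <- function(n, seed = NULL) {
  if (!is.finite(n) || n < 1) stop("sample_uniform_sphere: n >= 1")
  n <- as.integer(n)
  with_seed(seed, {
    x <- matrix(rnorm(3L * n), n, 3L)
    x / row_norms(x)
  })
}

#' von Mises-Fisher directions
#'
#' Samples from the von Mises-Fisher distribution on the sphere with mean
#' direction `mu` and concentration `kappa`, using the standard inversion of
#' the cosine component: `w = 1 + log(xi + (1 - xi) * exp(-2*kappa)) / kappa`
#' with `xi` uniform, combined with a uniform azimuth around `mu`.
#' `kappa = 0` reduces to the uniform distribution.
#'
#' @param n Number of directions (>= 1).
#' @param mu Mean direction (unit 3-vector). Default `c(0, 0, -1)`, the
#'   gravity pole used for partial-gravity concentration.
#' @param kappa Concentration parameter (>= 0).
#' @param seed Optional integer seed.
#' @return An `n x 3` matrix of unit rows.
#' @export
sample_vmf <- function(n, mu = c(0, 0, -1), kappa, seed = NULL) {
  if (!is.finite(n) || n < 1) stop("sample_vmf: n >= 1")
  if (!is.finite(kappa) || kappa < 0) stop("sample_vmf: kappa >= 0")
  if (length(mu) != 3L || abs(vec_norm(mu) - 1) > 1e-6)
    stop("sample_vmf: 'mu' must be a unit 3-vector")
  n <- as.integer(n)
  mu <- mu / vec_norm(mu)
  with_seed(seed, {
    xi <- runif(n)
    w <- if (kappa == 0) 2 * xi - 1
         else 1 + log(xi + (1 - xi) * exp(-2 * kappa)) / kappa
    w <- pmin(1, pmax(-1, w))
    phi <- runif(n, 0, 2 * pi)
    # orthonormal basis completing mu
    ref <- if (abs(mu[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    e1 <- ref - sum(ref * mu) * mu; e1 <- e1 / vec_norm(e1)
    e2 <- c(mu[2] * e1[3] - mu[3] * e1[2],
            mu[3] * e1[1] - mu[1] * e1[3],
            mu[1] * e1[2] - mu[2] * e1[1])
    r <- sqrt(pmax(0, 1 - w^2))
    u <- outer(w, mu) + outer(r * cos(phi), e1) + outer(r * sin(phi), e2)
    u / row_norms(u)
  })
}

# Uniform (Haar) random rotation from a normalized Gaussian quaternion.
# Uses the current RNG stream.
random_rotation_matrix <- function() {
  q <- rnorm(4); q <- q / vec_norm(q)
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), 3, 3, byrow = TRUE)
}

#' Mean resultant length of a direction sample
#'
#' The norm of the average of the unit vectors. For a gravity-direction path
#' this equals, by construction, the final residual gravity in units of g.
#'
#' @param points An `n x 3` matrix of unit vectors or an [direction_path()].
#' @return A scalar in `[0, 1]`.
#' @export
mean_resultant_length <- function(points) {
  if (inherits(points, "mgs_direction_path")) points <- direction_matrix(points)
  vec_norm(colMeans(as.matrix(points)))
}

#' Concentration parameter matching a mean resultant length
#'
#' Solves `coth(kappa) - 1/kappa = rho` for the von Mises-Fisher
#' concentration whose population mean resultant length equals `rho`. Used to
#' pick the partial-gravity concentration for a requested `target_g`.
#'
#' @param rho Mean resultant length in `[0, 1)`.
#' @return The concentration `kappa >= 0`.
#' @export
vmf_concentration <- function(rho) {
  if (!is.finite(rho) || rho < 0 || rho >= 1)
    stop("vmf_concentration: rho must lie in [0, 1)")
  if (rho < 1e-12) return(0)
  f <- function(k) 1 / tanh(k) - 1 / k - rho
  uniroot(f, lower = 1e-8, upper = 1e8, tol = 1e-12)$root
}
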