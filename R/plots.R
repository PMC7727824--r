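# Diagnostic figures: sphere density map and residual-gravity curve.

#' Density map of a direction path on the sphere
#'
#' Draws the equal-area histogram of [sphere_histogram()] in a cylindrical
#' equal-area projection (longitude vs. z): every drawn rectangle subtends
#' the same solid angle, so color directly encodes point density. Homogeneous
#' coverage appears flat; polar clustering appears as bright bands at the
#' top/bottom.
#'
#' @param points An `n x 3` matrix of unit vectors or an [direction_path()].
#' @param n_rings Number of latitude rings.
#' @param main Plot title.
#' @return The `mgs_sphere_hist`, invisibly.
#' @export
plot_sphere_density <- function(points, n_rings = 12L,
                                main = "Direction density (equal-area cells)") {
  h <- sphere_histogram(points, n_rings)
  cells <- h$cells
  cmax <- max(cells$count, 1L)
  pal <- grDevices::hcl.colors(64, "YlOrRd", rev = TRUE)
  graphics::plot(NULL, xlim = c(-pi, pi), ylim = c(-1, 1),
                 xlab = "longitude (rad)", ylab = "z", main = main)
  for (r in unique(cells$ring)) {
    cr <- cells[cells$ring == r, ]
    mr <- nrow(cr)
    brk <- seq(-pi, pi, length.out = mr + 1)
    graphics::rect(brk[cr$cell], cr$z_lo, brk[cr$cell + 1], cr$z_hi,
                   col = pal[pmax(1L, ceiling(cr$count / cmax * 64))],
                   border = NA)
  }
  invisible(h)
}

#' Residual-gravity curve
#'
#' Plots the magnitude of the running time-averaged gravity vector (units of
#' g) against time on a log scale, the standard diagnostic for nullification
#' quality.
#'
#' @param x An `mgs_residual_series` from [residual_gravity()].
#' @param ... Further arguments passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.mgs_residual_series <- function(x, ...) {
  graphics::plot(x$t, pmax(x$magnitude_g, 1e-12), type = "l", log = "y",
                 xlab = "time (s)", ylab = "|time-averaged gravity| (g)",
                 main = "Residual gravity", ...)
  graphics::abline(h = c(0.01, 1e-3), lty = 3, col = "grey40")
  invisible(x)
}
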