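#' Plot a kymograph as an image
#'
#' Angular position against time, intensity colour-coded.
#'
#' @param x a `kymo`.
#' @param col colour palette.
#' @param xlab,ylab,main usual graphics labels.
#' @param ... passed to [graphics::image()].
#' @export
plot.kymo <- function(x, col = grDevices::hcl.colors(64, "viridis"),
                      xlab = "angular position (rad)", ylab = "time (s)",
                      main = x$channel, ...) {
  graphics::image(x$phi, x$times, t(x$I), col = col, xlab = xlab,
                  ylab = ylab, main = main, useRaster = TRUE, ...)
  invisible(x)
}

#' Plot a dispersion relation
#'
#' Leading growth rate against wavenumber, with the oscillation frequency
#' of the leading eigenvalue on a second panel.
#'
#' @param x a `rac_dispersion`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.rac_dispersion <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  graphics::plot(x$modes$q, x$modes$re_sigma, type = "b",
                 xlab = "q (1/um)", ylab = "Re sigma (1/s)", ...)
  graphics::abline(h = 0, lty = 2)
  graphics::plot(x$modes$q, abs(x$modes$im_sigma), type = "b",
                 xlab = "q (1/um)", ylab = "|Im sigma| (1/s)", ...)
  invisible(x)
}
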