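# Base-graphics views of the main analysis outputs.

#' Plot a spacing density track
#'
#' @param density Track from [spacing_density()] (optionally with p-values
#'   from [resample_pvalues()]).
#' @param what "count" or "p" (plots -log10 p when available).
#' @param ... Passed to [graphics::plot()].
#' @export
plot_spacing_density <- function(density, what = c("count", "p"), ...) {
  what <- match.arg(what)
  if (what == "p") {
    if (is.null(density$p_value)) stopf("track carries no p-values")
    graphics::plot(density$position, -log10(density$p_value), type = "l",
                   xlab = "signed inter-motif distance (bases)",
                   ylab = "-log10 p", ...)
    ac <- attr(density, "alpha_corrected")
    if (!is.null(ac)) graphics::abline(h = -log10(ac), lty = 2)
  } else {
    graphics::plot(density$position, density$count, type = "l",
                   xlab = "signed inter-motif distance (bases)",
                   ylab = "pairs per 100-bp window", ...)
  }
  invisible(density)
}

#' Plot a curve of binding probability or signal versus motif copy number
#'
#' @param points Curve points from [probability_curve()] or
#'   [signal_curve()].
#' @param fit Optional \code{fit_result} overlay.
#' @param ... Passed to [graphics::plot()].
#' @export
plot_curve <- function(points, fit = NULL, ...) {
  graphics::plot(points$k, points$value, pch = 19,
                 xlab = "ETS motifs per promoter", ylab = "value", ...)
  if (!is.null(points$se))
    graphics::arrows(points$k, points$value - points$se,
                     points$k, points$value + points$se,
                     angle = 90, code = 3, length = 0.03)
  if (!is.null(fit)) {
    xs <- seq(min(points$k), max(points$k), length.out = 100)
    ys <- if (fit$model == "exponential") fit$a * exp(fit$b * xs)
          else fit$a + fit$b * xs
    graphics::lines(xs, ys, col = "red")
  }
  invisible(points)
}

#' Plot a helical-phase binding profile
#'
#' @param x A \code{phase_profile}.
#' @param ... Passed to [graphics::plot()].
#' @export
plot_phase_profile <- function(x, ...) {
  graphics::plot(x$profile$phase, x$profile$relative_binding, pch = 19,
                 xlab = "helical phase (degrees)",
                 ylab = "relative binding", ...)
  graphics::lines(x$profile$phase, x$profile$fitted, col = "red")
  graphics::lines(x$all$phase, x$all$relative_count, col = "darkgreen",
                  lty = 2)
  invisible(x)
}
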