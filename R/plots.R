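# Basic agreement graphics.

#' Bland-Altman plot with nonparametric limits
#'
#' Plots per-slide differences against pair means, the mean difference, and
#' the 2.5th/97.5th percentile limits of agreement from [bland_altman()].
#'
#' @param x,y paired score vectors.
#' @param ... passed to [graphics::plot()].
#' @return invisibly, the `ba_result`.
#' @export
plot_bland_altman <- function(x, y, ...) {
  ok <- is.finite(x) & is.finite(y)
  ba <- bland_altman(x, y)
  avg <- (x[ok] + y[ok]) / 2
  graphics::plot(avg, x[ok] - y[ok], xlab = "mean of pair",
                 ylab = "difference", ...)
  graphics::abline(h = ba$mean_diff, col = "blue")
  graphics::abline(h = c(ba$loa_low, ba$loa_high), col = "red", lty = 2)
  invisible(ba)
}
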