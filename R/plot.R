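#' Four-panel recalibration diagnostics
#'
#' Panel A: sequencing-error counts by read position, with the flagging
#' threshold as a dashed cyan line — positions above it received their own
#' model covariate. Panel B: relative frequency distributions of quality
#' scores before (solid blue) and after (dashed red) recalibration.
#' Panels C and D: reported versus empirical quality before and after,
#' points shaded by the frequency of the score (darker = more bases) with
#' the 45-degree line of perfect calibration and the FWSE annotated.
#'
#' @param x A fitted `recal_model` (with calibration tables).
#' @param ... Unused.
#' @return `x`, invisibly.
#' @export
plot.recal_model <- function(x, ...) {
  if (is.null(x$cal_before) || is.null(x$cal_after))
    stop("model carries no calibration tables; refit with recal_fit()")
  op <- par(mfrow = c(2, 2), mar = c(4.2, 4.2, 2.5, 1))
  on.exit(par(op), add = TRUE)

  counts <- x$flagged$counts
  plot(seq_along(counts), counts, type = "h", lwd = 2, col = "grey30",
       xlab = "read position", ylab = "# errors",
       main = "A. Errors by read position")
  abline(h = x$flagged$threshold, col = "cyan3", lty = 2, lwd = 2)

  b <- x$cal_before; a <- x$cal_after
  xlim <- range(b$quality, a$quality)
  plot(b$quality, b$frequency, type = "l", col = "blue", lwd = 2,
       xlim = xlim, ylim = c(0, max(b$frequency, a$frequency)),
       xlab = "quality score", ylab = "relative frequency",
       main = "B. Quality score distributions")
  lines(a$quality, a$frequency, col = "red", lwd = 2, lty = 2)
  legend("topleft", c("before", "after"), col = c("blue", "red"),
         lty = c(1, 2), lwd = 2, bty = "n")

  .plot_calibration(b, fwse(b), "C. Before recalibration", "blue")
  .plot_calibration(a, fwse(a), "D. After recalibration", "red")
  invisible(x)
}

.plot_calibration <- function(tab, fwse_value, main, shade) {
  lim <- c(0, max(tab$quality, tab$empirical_quality))
  alpha <- 0.15 + 0.85 * tab$frequency / max(tab$frequency)
  rgbv <- grDevices::col2rgb(shade) / 255
  cols <- grDevices::rgb(rgbv[1], rgbv[2], rgbv[3], alpha)
  plot(tab$quality, tab$empirical_quality, pch = 21, bg = cols, col = shade,
       xlim = lim, ylim = lim, xlab = "reported quality",
       ylab = "empirical quality", main = main)
  abline(0, 1, col = "grey50")
  text(lim[1], lim[2] * 0.95, sprintf("FWSE = %.2f", fwse_value),
       adj = 0, font = 2)
}

#' Write the diagnostic figure to a file
#'
#' @param model A fitted `recal_model`.
#' @param path Output path; the device is chosen from `format`.
#' @param format `"png"` or `"pdf"`.
#' @param width,height Figure size in inches.
#' @return `path`, invisibly.
#' @export
plot_diagnostics <- function(model, path, format = c("png", "pdf"),
                             width = 9, height = 8) {
  format <- match.arg(format)
  if (format == "png") {
    grDevices::png(path, width = width, height = height, units = "in",
                   res = 150)
  } else {
    grDevices::pdf(path, width = width, height = height)
  }
  on.exit(grDevices::dev.off(), add = TRUE)
  plot(model)
  invisible(path)
}
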