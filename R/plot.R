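#' Overlay pointwise confidence bands from one or more methods
#'
#' Draws the fitted dose-response curve with shaded pointwise confidence
#' bands, optionally overlaying several methods (profile likelihood, Wald,
#' bootstrap) for direct comparison, together with the observed group
#' proportions.
#'
#' @param curves A single `pointwise_ci` or a named list of them (names are
#'   used in the legend).
#' @param path Optional file path; when given, the plot is written as a PNG
#'   instead of drawn on the current device.
#' @param data Optional [dose_response_data()] whose observed proportions
#'   are added as points.
#' @param main Plot title.
#' @param width,height,res PNG device settings when `path` is used.
#' @return Invisibly, `NULL`.
#' @export
plot_bands <- function(curves, path = NULL, data = NULL,
                       main = "Pointwise confidence intervals",
                       width = 900, height = 600, res = 110) {
  if (inherits(curves, "pointwise_ci")) curves <- list(CI = curves)
  stopifnot(length(curves) >= 1, all(vapply(curves, inherits,
                                            logical(1), "pointwise_ci")))
  if (!is.null(path)) {
    grDevices::png(path, width = width, height = height, res = res)
    on.exit(grDevices::dev.off(), add = TRUE)
  }
  cols <- c("#1b6ca8", "#c0392b", "#27ae60", "#8e44ad")
  ylim <- range(0, 1, unlist(lapply(curves, function(cv)
    range(cv$lower, cv$upper, na.rm = TRUE))))
  base <- curves[[1L]]
  graphics::plot(base$dose, base$estimate, type = "n",
                 xlab = "Dose", ylab = "Expected response",
                 ylim = ylim, main = main)
  graphics::abline(h = c(0, 1), col = "grey80", lty = 3)
  for (j in seq_along(curves)) {
    cv <- curves[[j]]; col <- cols[(j - 1L) %% length(cols) + 1L]
    ok <- is.finite(cv$lower) & is.finite(cv$upper)
    graphics::polygon(c(cv$dose[ok], rev(cv$dose[ok])),
                      c(cv$lower[ok], rev(cv$upper[ok])),
                      col = grDevices::adjustcolor(col, 0.15), border = NA)
    graphics::lines(cv$dose, cv$lower, col = col, lty = 2)
    graphics::lines(cv$dose, cv$upper, col = col, lty = 2)
  }
  graphics::lines(base$dose, base$estimate, lwd = 2)
  if (!is.null(data))
    graphics::points(data$dose, data$responders / data$total, pch = 19)
  graphics::legend("bottomright", bty = "n",
                   legend = names(curves), lty = 2,
                   col = cols[seq_along(curves)])
  invisible(NULL)
}

#' @export
plot.pointwise_ci <- function(x, ...) plot_bands(x, ...)
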