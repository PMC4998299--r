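#' Four-quadrant plot of classified changes
#'
#' Scatter of (delta reference, delta test) for each change, coloured by
#' its interchangeability category, with the quadrant axes and the line of
#' identity.
#'
#' @param changes data frame with columns `delta_rm`, `delta_tm` and
#'   (optionally) `category`; uncategorised points are drawn grey.
#' @param main plot title.
#' @param legend draw the category legend.
#' @param ... further arguments to [graphics::plot()].
#' @return the input, invisibly. Empty input draws an empty frame with a
#'   warning.
#' @export
plot_four_quadrant <- function(changes, main = NULL, legend = TRUE, ...) {
  stopifnot(is.data.frame(changes))
  cols <- tim_colors()
  if (nrow(changes) == 0L) {
    warning("no changes to plot", call. = FALSE)
    graphics::plot(0, 0, type = "n", xlab = expression(Delta * RM),
                   ylab = expression(Delta * TM), main = main)
    return(invisible(changes))
  }
  col <- if ("category" %in% names(changes)) {
    unname(cols[as.character(changes$category)])
  } else {
    rep("grey40", nrow(changes))
  }
  col[is.na(col)] <- "grey40"
  lim <- range(c(changes$delta_rm, changes$delta_tm, 0), na.rm = TRUE)
  graphics::plot(changes$delta_rm, changes$delta_tm, col = col, pch = 16,
                 xlim = lim, ylim = lim, xlab = expression(Delta * RM),
                 ylab = expression(Delta * TM), main = main, ...)
  graphics::abline(h = 0, v = 0, col = "grey70")
  graphics::abline(0, 1, lty = 2)
  if (legend) {
    graphics::legend("topleft", legend = names(cols), col = unname(cols),
                     pch = 16, bty = "n", cex = 0.8)
  }
  invisible(changes)
}

#' Polar plot of classified changes
#'
#' Each change is drawn as a point at its polar radius and its angle from
#' the line of identity (0 degrees = perfect trend agreement, drawn
#' horizontal), coloured by interchangeability category, with reference
#' rays at +/- 30 degrees.
#'
#' @param changes data frame with `delta_rm`, `delta_tm` and optional
#'   `category`.
#' @param exclusion_radius drop change vectors shorter than this radius.
#' @param fold see [to_polar()].
#' @param main plot title.
#' @param legend draw the category legend.
#' @param ... further arguments to [graphics::points()].
#' @return the polar coordinates used, invisibly.
#' @export
plot_polar <- function(changes, exclusion_radius = 0, fold = TRUE,
                       main = NULL, legend = TRUE, ...) {
  stopifnot(is.data.frame(changes))
  cols <- tim_colors()
  pol <- if (nrow(changes)) {
    suppressWarnings(to_polar(changes$delta_rm, changes$delta_tm, fold = fold))
  } else {
    data.frame(radius = numeric(), angle = numeric())
  }
  keep <- !is.na(pol$radius) & pol$radius >= exclusion_radius
  rmax <- if (any(keep)) max(pol$radius[keep]) else 1
  graphics::plot(NA, xlim = c(-rmax, rmax) * 1.05, ylim = c(-rmax, rmax) * 1.05,
                 asp = 1, xlab = "magnitude of change (units)", ylab = "",
                 main = main, axes = FALSE)
  graphics::axis(1)
  theta <- seq(-pi, pi, length.out = 241)
  for (r in pretty(c(0, rmax))[-1]) {
    graphics::lines(r * cos(theta), r * sin(theta), col = "grey85")
  }
  graphics::abline(h = 0, col = "grey60")
  for (a in c(-30, 30) * pi / 180) {
    graphics::segments(0, 0, rmax * cos(a), rmax * sin(a),
                       lty = 2, col = "grey40")
  }
  if (!any(keep)) {
    warning("no change vectors to plot after exclusion", call. = FALSE)
    return(invisible(pol))
  }
  col <- if ("category" %in% names(changes)) {
    unname(cols[as.character(changes$category)])
  } else {
    rep("grey40", nrow(changes))
  }
  col[is.na(col)] <- "grey40"
  a <- pol$angle[keep] * pi / 180
  graphics::points(pol$radius[keep] * cos(a), pol$radius[keep] * sin(a),
                   col = col[keep], pch = 16, ...)
  if (legend) {
    graphics::legend("topleft", legend = names(cols), col = unname(cols),
                     pch = 16, bty = "n", cex = 0.8)
  }
  invisible(pol)
}
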