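#' Fit a trend interchangeability analysis
#'
#' The main entry point: takes serial paired measurements of one or more
#' test devices against a common reference method, extracts consecutive
#' changes per subject–device series, classifies each change with the
#' two-step interchangeability procedure (see [classify_change()]) and
#' computes per-device trend interchangeability rates.
#'
#' @param data a `"paired_series"` object from [read_series()],
#'   [as_paired_series()] or [simulate_series()]; or a long data frame,
#'   which is passed through [as_paired_series()] first.
#' @param rc repeatability coefficient of the reference method, as a
#'   fraction (`0.05`) or a percentage (`5`).
#' @param symmetric_intercepts see [interchangeability_lines()].
#' @param cols,drop_first forwarded to [as_paired_series()] when `data`
#'   is a plain data frame.
#' @return an object of class `"tim"`: a list with components
#'   \describe{
#'     \item{changes}{data frame of classified changes (one row each, with
#'       `category` and `color` columns appended).}
#'     \item{rc}{the repeatability coefficient as a fraction.}
#'     \item{series}{the input paired series (with its exclusion log).}
#'     \item{symmetric_intercepts}{the line-intercept convention used.}
#'     \item{call}{the matched call.}
#'   }
#'   Methods: [print.tim()], [summary.tim()], [plot.tim()].
#' @examples
#' d <- simulate_series(tim_design(n_patients = 30, seed = 1))
#' fit <- tim(d, rc = 0.05)
#' summary(fit)
#' @export
tim <- function(data, rc,
                symmetric_intercepts = FALSE,
                cols = c(subject = "subject", device = "device",
                         time = "time", rm = "rm", tm = "tm"),
                drop_first = FALSE) {
  rc <- repeatability_coef(rc)
  if (!inherits(data, "paired_series")) {
    data <- as_paired_series(data, cols = cols, drop_first = drop_first)
  }
  changes <- extract_changes(data)
  if (nrow(changes) == 0L) {
    stop("no change observations: need at least 2 retained pairs in ",
         "some subject-device series", call. = FALSE)
  }
  changes$category <- classify_change(
    changes$rm1, changes$tm1, changes$rm2, changes$tm2,
    rc = rc, symmetric_intercepts = symmetric_intercepts
  )
  changes$color <- unname(tim_colors()[as.character(changes$category)])
  structure(
    list(changes = changes, rc = rc, series = data,
         symmetric_intercepts = symmetric_intercepts,
         call = match.call()),
    class = "tim"
  )
}

#' @export
print.tim <- function(x, ...) {
  cat("Trend interchangeability analysis\n")
  cat(sprintf("  repeatability coefficient: %g%%\n", 100 * x$rc))
  cat(sprintf("  changes: %d from %d subject(s), %d device(s)\n",
              nrow(x$changes), length(unique(x$changes$subject)),
              length(unique(x$changes$device))))
  print(table(x$changes$category))
  invisible(x)
}

#' Summarise a trend interchangeability fit
#'
#' Per-device category counts and trend interchangeability rates, pooled
#' counts across devices, and (when at least two devices have
#' interpretable changes) the chi-square homogeneity test of the rate
#' across devices.
#'
#' @param object a `"tim"` fit.
#' @param ... unused.
#' @return an object of class `"summary.tim"`: a list with `devices`
#'   (per-device summary data frame), `pooled` (one-row summary over all
#'   devices), `rc` and `chisq` (an `htest` or `NULL`).
#' @export
summary.tim <- function(object, ...) {
  ch <- object$changes
  devs <- sort(unique(ch$device))
  per <- do.call(rbind, lapply(devs, function(d) {
    s <- summarize_changes(ch$category[ch$device == d])
    cbind(device = d, s, stringsAsFactors = FALSE)
  }))
  rownames(per) <- NULL
  pooled <- summarize_changes(ch$category)
  chisq <- NULL
  if (sum(per$n_interpretable > 0) >= 2) {
    chisq <- suppressWarnings(compare_devices(per))
  }
  structure(list(devices = per, pooled = pooled, rc = object$rc,
                 chisq = chisq),
            class = "summary.tim")
}

#' @export
print.summary.tim <- function(x, digits = 3, ...) {
  cat(sprintf("Trend interchangeability summary (RC = %g%%)\n\n", 100 * x$rc))
  tab <- x$devices
  tab$tim_rate <- round(tab$tim_rate, digits)
  print(tab, row.names = FALSE)
  if (nrow(x$devices) > 1) {
    cat("\nPooled over devices:\n")
    p <- x$pooled
    p$tim_rate <- round(p$tim_rate, digits)
    print(p, row.names = FALSE)
  }
  if (!is.null(x$chisq)) {
    cat(sprintf(
      "\nChi-square homogeneity of rate across devices: X2 = %.3f, df = %d, p = %.3f\n",
      x$chisq$statistic, x$chisq$parameter, x$chisq$p.value))
  }
  invisible(x)
}

#' Diagnostic plots for a trend interchangeability fit
#'
#' `type = "four_quadrant"` draws the classified changes in the
#' (delta reference, delta test) plane with the line of identity;
#' `type = "polar"` draws the polar-plot view with reference rays at
#' +/- 30 degrees. Both use the fixed category colour code (blue
#' uninterpretable, red noninterchangeable, orange gray zone, green
#' interchangeable). With several devices, one panel per device is drawn.
#'
#' @param x a `"tim"` fit.
#' @param type which view to draw.
#' @param device optional device label(s) to restrict to.
#' @param exclusion_radius for the polar view, drop changes with vector
#'   magnitude below this radius (in measurement units).
#' @param ... passed on to the underlying plot function.
#' @return `x`, invisibly.
#' @export
plot.tim <- function(x, type = c("four_quadrant", "polar"), device = NULL,
                     exclusion_radius = 0, ...) {
  type <- match.arg(type)
  ch <- x$changes
  if (!is.null(device)) ch <- ch[ch$device %in% device, , drop = FALSE]
  devs <- sort(unique(ch$device))
  if (length(devs) > 1) {
    op <- graphics::par(mfrow = grDevices::n2mfrow(length(devs)))
    on.exit(graphics::par(op))
  }
  for (d in devs) {
    sub <- ch[ch$device == d, , drop = FALSE]
    main <- if (length(devs) > 1) d else NULL
    if (type == "four_quadrant") {
      plot_four_quadrant(sub, main = main, ...)
    } else {
      plot_polar(sub, exclusion_radius = exclusion_radius, main = main, ...)
    }
  }
  invisible(x)
}
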