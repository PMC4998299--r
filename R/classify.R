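# Relative tolerance for every boundary comparison in the classification
# geometry; far below any physiological measurement resolution.
.TIM_TOL <- 1e-9

.tol <- function(...) {
  m <- Reduce(pmax, lapply(list(...), abs))
  .TIM_TOL * pmax(1, m)
}

#' Category levels and colour code
#'
#' The four outcomes of the trend interchangeability classification, in
#' severity order, and their fixed colour code (blue, red, orange, green)
#' as used in all diagnostic plots.
#'
#' @return `tim_categories()` returns the four category labels;
#'   `tim_colors()` returns a named character vector mapping each category
#'   to its colour.
#' @examples
#' tim_colors()[tim_categories()]
#' @export
tim_categories <- function() {
  c("uninterpretable", "noninterchangeable", "gray_zone", "interchangeable")
}

#' @rdname tim_categories
#' @export
tim_colors <- function() {
  c(
    uninterpretable    = "blue",
    noninterchangeable = "red",
    gray_zone          = "orange",
    interchangeable    = "green"
  )
}

.as_category <- function(x) factor(x, levels = tim_categories())

#' Repeatability coefficient of the reference method
#'
#' Normalises a repeatability coefficient to a fraction in (0, 1). Values
#' greater than or equal to 1 are interpreted as percentages (so `5` and
#' `0.05` both denote a 5% repeatability).
#'
#' @param coefficient repeatability coefficient, as a fraction in (0, 1)
#'   or a percentage in [1, 100).
#' @return a numeric scalar fraction in (0, 1).
#' @examples
#' repeatability_coef(5)    # 0.05
#' repeatability_coef(0.2)  # 0.2
#' @export
repeatability_coef <- function(coefficient) {
  if (length(coefficient) != 1L || !is.numeric(coefficient) ||
      !is.finite(coefficient)) {
    stop("`coefficient` must be a single finite number", call. = FALSE)
  }
  if (coefficient <= 0) {
    stop("repeatability coefficient must be positive", call. = FALSE)
  }
  if (coefficient >= 1) {
    if (coefficient >= 100) {
      stop("repeatability coefficient must be below 100%", call. = FALSE)
    }
    coefficient <- coefficient / 100
  }
  coefficient
}

#' Precision interval of a single reference measurement
#'
#' The interval `value +/- |value| * rc`: the range within which a repeat
#' of the same true quantity by the reference method is expected to fall.
#' The absolute value keeps `lo <= hi` for negative measurements.
#'
#' @param value measurement value(s); must be finite.
#' @param rc repeatability coefficient (fraction or percent; see
#'   [repeatability_coef()]).
#' @return a two-column matrix with columns `lo` and `hi`, one row per value.
#' @examples
#' precision_interval(4, rc = 0.05)   # 3.8 .. 4.2
#' precision_interval(2.5, rc = 0.2)  # 2.0 .. 3.0
#' @export
precision_interval <- function(value, rc) {
  rc <- repeatability_coef(rc)
  if (!is.numeric(value) || any(!is.finite(value))) {
    stop("`value` must be finite", call. = FALSE)
  }
  half <- abs(value) * rc
  cbind(lo = value - half, hi = value + half)
}

#' Interpretability screen for a change in the reference method
#'
#' A change between two reference measurements is interpretable only when
#' their precision intervals do not overlap, so that a true change can be
#' asserted despite measurement repeatability. Intervals that touch at a
#' single boundary point count as overlapping (conservative).
#'
#' @param rm1,rm2 first and second reference-method values (vectorised).
#' @param rc repeatability coefficient.
#' @return logical vector: `TRUE` where the change is interpretable.
#' @examples
#' is_interpretable(4, 5, rc = 0.05)    # TRUE
#' is_interpretable(4, 4.2, rc = 0.20)  # FALSE: intervals overlap
#' @export
is_interpretable <- function(rm1, rm2, rc) {
  rc <- repeatability_coef(rc)
  i1 <- precision_interval(rm1, rc)
  i2 <- precision_interval(rm2, rc)
  tol <- .tol(rm1, rm2)
  # disjoint only when separated by more than the boundary tolerance
  (i1[, "hi"] < i2[, "lo"] - tol) | (i2[, "hi"] < i1[, "lo"] - tol)
}

#' Interchangeability lines anchored at the first paired measurement
#'
#' The two lines bounding the zone of changes consistent with the first
#' pair `(rm1, tm1)` given the reference repeatability. In the plane where
#' `X` is the reference-method coordinate and `Y` the test-method coordinate
#' of the second pair, they are
#' `X = Y (1 + RC) + (1 + RC) (rm1 - tm1)` and
#' `X = Y (1 - RC) + (1 + RC) (rm1 - tm1)`.
#'
#' The shared `(1 + RC)` intercept on both lines is the published form;
#' `symmetric_intercepts = TRUE` switches the second line's intercept factor
#' to `(1 - RC)`, the symmetric variant.
#'
#' @param rm1,tm1 the first paired measurement (reference, test).
#' @param rc repeatability coefficient.
#' @param symmetric_intercepts use `(1 - RC)` for the lower line's intercept
#'   factor instead of the published `(1 + RC)`.
#' @return a list of class `"interchangeability_lines"` with components
#'   `upper` and `lower`, each `c(slope, intercept)`, plus `rc`.
#' @examples
#' interchangeability_lines(rm1 = 4, tm1 = 3, rc = 0.05)
#' @export
interchangeability_lines <- function(rm1, tm1, rc, symmetric_intercepts = FALSE) {
  rc <- repeatability_coef(rc)
  off_up <- (1 + rc) * (rm1 - tm1)
  off_lo <- if (symmetric_intercepts) (1 - rc) * (rm1 - tm1) else off_up
  structure(
    list(
      upper = c(slope = 1 + rc, intercept = off_up),
      lower = c(slope = 1 - rc, intercept = off_lo),
      rc = rc
    ),
    class = "interchangeability_lines"
  )
}

#' @export
print.interchangeability_lines <- function(x, ...) {
  cat("Interchangeability lines (X = reference, Y = test):\n")
  cat(sprintf("  upper: X = %.6g * Y + %.6g\n", x$upper["slope"], x$upper["intercept"]))
  cat(sprintf("  lower: X = %.6g * Y + %.6g\n", x$lower["slope"], x$lower["intercept"]))
  invisible(x)
}

# Zone bounds along the reference axis at test-axis coordinate tm2.
# Vectorised over rm1/tm1/tm2.
.zone_bounds <- function(rm1, tm1, tm2, rc, symmetric_intercepts = FALSE) {
  off_up <- (1 + rc) * (rm1 - tm1)
  off_lo <- if (symmetric_intercepts) (1 - rc) * (rm1 - tm1) else off_up
  b1 <- (1 + rc) * tm2 + off_up
  b2 <- (1 - rc) * tm2 + off_lo
  cbind(lo = pmin(b1, b2), hi = pmax(b1, b2))
}

#' Position of the second pair relative to the interchangeability zone
#'
#' Evaluates both interchangeability lines at the second pair's test-axis
#' coordinate `tm2` and locates the second reference value `rm2` relative
#' to the closed zone between them: `"inside"` the zone,
#' `"boundary_overlap"` when `rm2` itself is outside but its precision
#' interval (taken along the reference axis at fixed `Y = tm2`) still
#' reaches the zone, or `"outside"`.
#'
#' @param rm2,tm2 the second paired measurement (vectorised).
#' @param lines an [interchangeability_lines()] object built from the same
#'   change's first pair.
#' @return character vector in `{"inside", "boundary_overlap", "outside"}`.
#' @examples
#' ln <- interchangeability_lines(rm1 = 4, tm1 = 3, rc = 0.05)
#' region_status(rm2 = 6, tm2 = 5, lines = ln)  # "inside"
#' region_status(rm2 = 8, tm2 = 5, lines = ln)  # "outside"
#' @export
region_status <- function(rm2, tm2, lines) {
  stopifnot(inherits(lines, "interchangeability_lines"))
  rc <- lines$rc
  b1 <- unname(lines$upper["slope"] * tm2 + lines$upper["intercept"])
  b2 <- unname(lines$lower["slope"] * tm2 + lines$lower["intercept"])
  zone_lo <- pmin(b1, b2)
  zone_hi <- pmax(b1, b2)
  pi2 <- precision_interval(rm2, rc)
  tol <- .tol(rm2, tm2, zone_lo, zone_hi)
  inside <- rm2 >= zone_lo - tol & rm2 <= zone_hi + tol
  touches <- pi2[, "hi"] >= zone_lo - tol & pi2[, "lo"] <= zone_hi + tol
  unname(ifelse(inside, "inside", ifelse(touches, "boundary_overlap", "outside")))
}

#' Classify changes between consecutive paired measurements
#'
#' The two-step trend interchangeability classification of a change from
#' `(rm1, tm1)` to `(rm2, tm2)`:
#'
#' 1. *Interpretability screen*: if the precision intervals of `rm1` and
#'    `rm2` overlap, the change is `uninterpretable` (the reference method
#'    itself cannot assert that anything changed); the test values are
#'    never consulted.
#' 2. *Interchangeability zone*: otherwise the second pair is located
#'    relative to the zone between the two interchangeability lines
#'    anchored at the first pair — inside it the change is
#'    `interchangeable`, outside it but with the precision interval of
#'    `rm2` still reaching the zone it is in the `gray_zone`, and
#'    otherwise it is `noninterchangeable`.
#'
#' All four inputs are vectorised and recycled to a common length.
#'
#' @param rm1,tm1,rm2,tm2 the two consecutive paired measurements.
#' @param rc repeatability coefficient of the reference method.
#' @param symmetric_intercepts see [interchangeability_lines()].
#' @param warn_nonpositive warn when a measurement is zero or negative
#'   (the geometry is motivated by positive physiological quantities).
#' @return a factor with levels [tim_categories()]; changes with any
#'   missing member are returned as `NA` (excluded, not classified).
#' @examples
#' classify_change(rm1 = 3, tm1 = 3, rm2 = 5, tm2 = 5, rc = 0.05)
#' classify_change(rm1 = 4, tm1 = 3, rm2 = 8, tm2 = 5, rc = 0.05)
#' @export
classify_change <- function(rm1, tm1, rm2, tm2, rc,
                            symmetric_intercepts = FALSE,
                            warn_nonpositive = TRUE) {
  rc <- repeatability_coef(rc)
  n <- max(length(rm1), length(tm1), length(rm2), length(tm2))
  rm1 <- rep_len(rm1, n); tm1 <- rep_len(tm1, n)
  rm2 <- rep_len(rm2, n); tm2 <- rep_len(tm2, n)

  ok <- is.finite(rm1) & is.finite(tm1) & is.finite(rm2) & is.finite(tm2)
  out <- rep(NA_character_, n)
  if (any(ok)) {
    if (warn_nonpositive &&
        any(c(rm1[ok], tm1[ok], rm2[ok], tm2[ok]) <= 0)) {
      warning("non-positive measurement(s): the multiplicative precision ",
              "interval and the interchangeability geometry are motivated ",
              "by positive quantities", call. = FALSE)
    }
    interp <- is_interpretable(rm1[ok], rm2[ok], rc)
    zone <- .zone_bounds(rm1[ok], tm1[ok], tm2[ok], rc, symmetric_intercepts)
    pi2 <- precision_interval(rm2[ok], rc)
    tol <- .tol(rm2[ok], tm2[ok], zone[, "lo"], zone[, "hi"])
    inside <- rm2[ok] >= zone[, "lo"] - tol & rm2[ok] <= zone[, "hi"] + tol
    touches <- pi2[, "hi"] >= zone[, "lo"] - tol & pi2[, "lo"] <= zone[, "hi"] + tol
    cls <- ifelse(!interp, "uninterpretable",
                  ifelse(inside, "interchangeable",
                         ifelse(touches, "gray_zone", "noninterchangeable")))
    out[ok] <- cls
  }
  .as_category(out)
}
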