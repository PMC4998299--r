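#' Four-quadrant concordance rate
#'
#' The fraction of paired changes lying in the two quadrants of agreement
#' (both methods moving in the same direction), after removing changes
#' inside a central exclusion zone of clinically insignificant changes.
#' The exclusion threshold may be an absolute value in measurement units
#' or a percentage of the mean absolute change magnitude (a scale-free
#' convention, since published percentage rules refer to instrument scale
#' that a bare change pair does not carry). No exclusion is applied by
#' default: the published zone choices are arbitrary and must be opted
#' into.
#'
#' @param delta_rm,delta_tm paired changes in the reference and test
#'   method. `delta_tm` may be omitted when `delta_rm` is a two-column
#'   object (or a data frame with `delta_rm`/`delta_tm` columns).
#' @param exclusion threshold of the central exclusion zone (0 = none).
#'   A change is excluded when *both* |delta_rm| and |delta_tm| fall
#'   strictly below the threshold.
#' @param exclusion_type `"absolute"` (units) or `"percent"` (% of the
#'   mean absolute change over both methods).
#' @return a list with `rate` (concordant / remaining; `NA` and a warning
#'   when everything is excluded), `n_used`, `n_excluded` and `threshold`
#'   (the absolute threshold actually applied).
#' @examples
#' concordance_rate(c(1, -1), c(1, -1))$rate            # 1
#' concordance_rate(c(0.3, 1, -1), c(0.3, 1, 1), exclusion = 0.5)$rate  # 0.5
#' @export
concordance_rate <- function(delta_rm, delta_tm = NULL, exclusion = 0,
                             exclusion_type = c("absolute", "percent")) {
  exclusion_type <- match.arg(exclusion_type)
  if (is.null(delta_tm)) {
    if (is.data.frame(delta_rm)) {
      delta_tm <- delta_rm$delta_tm
      delta_rm <- delta_rm$delta_rm
    } else {
      delta_tm <- delta_rm[, 2]
      delta_rm <- delta_rm[, 1]
    }
  }
  stopifnot(length(delta_rm) == length(delta_tm), exclusion >= 0)
  keep <- is.finite(delta_rm) & is.finite(delta_tm)
  delta_rm <- delta_rm[keep]
  delta_tm <- delta_tm[keep]
  thr <- if (exclusion_type == "percent") {
    exclusion / 100 * mean(abs(c(delta_rm, delta_tm)))
  } else {
    exclusion
  }
  inside <- abs(delta_rm) < thr & abs(delta_tm) < thr
  used_rm <- delta_rm[!inside]
  used_tm <- delta_tm[!inside]
  n_used <- length(used_rm)
  rate <- if (n_used == 0) {
    warning("all changes fall inside the exclusion zone; ",
            "concordance rate undefined", call. = FALSE)
    NA_real_
  } else {
    sum(used_rm * used_tm > 0) / n_used
  }
  list(rate = rate, n_used = n_used, n_excluded = sum(inside), threshold = thr)
}

#' Polar coordinates of a paired change
#'
#' Represents each change pair as a vector: the radius is its Euclidean
#' magnitude and the angle is measured from the line of identity Y = X
#' (positive when the test method's change exceeds the reference's).
#' With `fold = TRUE` (default) vectors pointing into the lower-left
#' half-plane — both methods decreasing — are reflected through the
#' origin before the angle is taken, so that a concordant decrease reads
#' the same as a concordant increase; `fold = FALSE` keeps the raw angle.
#'
#' @param delta_rm,delta_tm paired changes (vectorised); `delta_tm` may
#'   be omitted as in [concordance_rate()].
#' @param fold reflect lower-left half-plane vectors through the origin.
#' @return a data frame with columns `radius` and `angle` (degrees in
#'   \[-180, 180\]). Zero-length vectors yield `NA` with a warning.
#' @examples
#' to_polar(1, 1)$angle    # 0: on the line of identity
#' to_polar(1, 0)$angle    # -45
#' to_polar(-1, -1)$angle  # 0 under the fold convention
#' @export
to_polar <- function(delta_rm, delta_tm = NULL, fold = TRUE) {
  if (is.null(delta_tm)) {
    if (is.data.frame(delta_rm)) {
      delta_tm <- delta_rm$delta_tm
      delta_rm <- delta_rm$delta_rm
    } else {
      delta_tm <- delta_rm[, 2]
      delta_rm <- delta_rm[, 1]
    }
  }
  stopifnot(length(delta_rm) == length(delta_tm))
  radius <- sqrt(delta_rm^2 + delta_tm^2)
  zero <- radius == 0
  if (any(zero, na.rm = TRUE)) {
    warning(sum(zero, na.rm = TRUE),
            " zero-length change vector(s) excluded (angle undefined)",
            call. = FALSE)
  }
  drm <- delta_rm
  dtm <- delta_tm
  if (fold) {
    flip <- !is.na(drm) & !is.na(dtm) & (drm + dtm) < 0
    drm[flip] <- -drm[flip]
    dtm[flip] <- -dtm[flip]
  }
  angle <- atan2(dtm, drm) * 180 / pi - 45
  angle <- ((angle + 180) %% 360) - 180
  angle[zero] <- NA_real_
  radius[zero] <- NA_real_
  data.frame(radius = radius, angle = angle)
}

#' Polar-plot agreement statistics
#'
#' Angular bias (mean polar angle) and radial limits of agreement
#' (1.96 standard deviations of the angle) of a set of change vectors,
#' after removing vectors shorter than `exclusion_radius`. The customary
#' acceptance thresholds are an angular bias within +/- 5 degrees and
#' radial limits within +/- 30 degrees. Plain (non-circular) mean and SD
#' are used: angles of interest cluster near zero, which those thresholds
#' presuppose.
#'
#' @param points a data frame from [to_polar()] (columns `radius`,
#'   `angle`), or anything [to_polar()] accepts.
#' @param exclusion_radius drop vectors with magnitude below this value
#'   (units of measurement; e.g. 0.5 L/min has been used for cardiac
#'   output).
#' @return a list with `angular_bias`, `radial_loa` (both degrees; `NA`
#'   with a warning when fewer than 2 vectors survive), `n_used` and
#'   `n_excluded`.
#' @examples
#' p <- to_polar(c(1, 2), c(1.2, 1.8))
#' polar_stats(p)
#' @export
polar_stats <- function(points, exclusion_radius = 0) {
  if (!(is.data.frame(points) && all(c("radius", "angle") %in% names(points)))) {
    points <- to_polar(points)
  }
  ok <- !is.na(points$radius) & !is.na(points$angle)
  pts <- points[ok, , drop = FALSE]
  inside <- pts$radius < exclusion_radius
  pts <- pts[!inside, , drop = FALSE]
  n_used <- nrow(pts)
  if (n_used < 2L) {
    warning("fewer than 2 change vectors survive exclusion; ",
            "polar statistics undefined", call. = FALSE)
    return(list(angular_bias = NA_real_, radial_loa = NA_real_,
                n_used = n_used, n_excluded = sum(inside)))
  }
  list(
    angular_bias = mean(pts$angle),
    radial_loa = 1.96 * stats::sd(pts$angle),
    n_used = n_used,
    n_excluded = sum(inside)
  )
}
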