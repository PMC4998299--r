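#' Design of a synthetic paired-series study
#'
#' Describes the simulation emulating a monitor-validation dataset:
#' patients are split evenly across a small number of value ranges, and
#' each patient contributes a short series of simultaneous
#' (reference, test) measurement pairs drawn from a multivariate normal
#' distribution centred at the patient's range.
#'
#' The default design has 150 patients, 3 values (hence 2 changes) per
#' patient and range centres 2.5, 3.5 and 5 units, 50 patients per range.
#' The per-range covariance matrices are built from a per-range standard
#' deviation (defaults 1.5, 1.2 and 1.0 units — decreasing with the range
#' centre), a within-time correlation between the reference and test
#' readings (`rho_method`, default 0.9) and an across-time correlation
#' (`rho_time`, default 0.2), combined as a Kronecker product so each
#' matrix is positive semi-definite by construction. An explicit
#' `covariance_spec` (list of one `2v x 2v` matrix per range, variables
#' ordered rm, tm within each time) overrides this.
#'
#' @param n_patients number of patients; must be divisible by the number
#'   of range centres under the balanced default.
#' @param values_per_patient pairs per patient (changes per patient is one
#'   less).
#' @param range_centers centre of each value range, in measurement units.
#' @param sigma per-range standard deviation(s), recycled across ranges.
#' @param rho_method correlation between rm and tm at the same time.
#' @param rho_time correlation across time points.
#' @param covariance_spec optional list of full per-range covariance
#'   matrices, overriding `sigma`/`rho_method`/`rho_time`.
#' @param seed integer seed making [simulate_series()] reproducible.
#' @return an object of class `"tim_design"`.
#' @examples
#' d <- tim_design(n_patients = 30, seed = 42)
#' @export
tim_design <- function(n_patients = 150,
                       values_per_patient = 3,
                       range_centers = c(2.5, 3.5, 5),
                       sigma = c(1.5, 1.2, 1.0),
                       rho_method = 0.9,
                       rho_time = 0.2,
                       covariance_spec = NULL,
                       seed = NULL) {
  k <- length(range_centers)
  stopifnot(n_patients >= 1, values_per_patient >= 2, k >= 1)
  if (n_patients %% k != 0) {
    stop("`n_patients` must be divisible by the number of range centers ",
         "in the balanced design", call. = FALSE)
  }
  p <- 2L * values_per_patient
  if (is.null(covariance_spec)) {
    sigma <- rep_len(sigma, k)
    M <- matrix(rho_method, 2, 2); diag(M) <- 1
    Tm <- matrix(rho_time, values_per_patient, values_per_patient); diag(Tm) <- 1
    covariance_spec <- lapply(seq_len(k), function(i) {
      sigma[i]^2 * kronecker(Tm, M)
    })
  }
  stopifnot(length(covariance_spec) == k)
  for (S in covariance_spec) {
    if (!is.matrix(S) || any(dim(S) != p) || !isTRUE(all.equal(S, t(S)))) {
      stop("each covariance matrix must be symmetric ", p, "x", p, call. = FALSE)
    }
    ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < -1e-8 * max(abs(ev), 1)) {
      stop("covariance matrix is not positive semi-definite", call. = FALSE)
    }
  }
  structure(
    list(n_patients = n_patients, values_per_patient = values_per_patient,
         range_centers = range_centers, covariance_spec = covariance_spec,
         seed = seed),
    class = "tim_design"
  )
}

#' @export
print.tim_design <- function(x, ...) {
  cat(sprintf(
    "Synthetic paired-series design: %d patients x %d values, ranges %s\n",
    x$n_patients, x$values_per_patient,
    paste(x$range_centers, collapse = "/")))
  invisible(x)
}

#' Generate a synthetic paired-series dataset
#'
#' Draws the design's patients from their per-range multivariate normal
#' distributions. With the default design this yields 150 patients with 3
#' paired values each — 300 change observations. Output is fully
#' reproducible from the design's seed.
#'
#' @param design a [tim_design()] object.
#' @return a `"paired_series"` object with synthetic subjects
#'   `P001, P002, ...` on a single device `"TM"`.
#' @examples
#' s <- simulate_series(tim_design(n_patients = 6, seed = 1))
#' nrow(s)  # 18 pairs
#' @export
simulate_series <- function(design) {
  stopifnot(inherits(design, "tim_design"))
  if (!is.null(design$seed)) set.seed(design$seed)
  k <- length(design$range_centers)
  per_range <- design$n_patients / k
  v <- design$values_per_patient

  blocks <- lapply(seq_len(k), function(i) {
    mu <- rep(design$range_centers[i], 2L * v)
    MASS::mvrnorm(n = per_range, mu = mu, Sigma = design$covariance_spec[[i]])
  })
  draws <- do.call(rbind, blocks)  # one row per patient: rm1,tm1,rm2,tm2,...

  n <- design$n_patients
  subject <- sprintf("P%03d", rep(seq_len(n), each = v))
  time <- rep(seq_len(v), times = n)
  rm_idx <- seq(1L, 2L * v, by = 2L)
  tm_idx <- rm_idx + 1L
  df <- data.frame(
    subject = subject,
    device = "TM",
    time = time,
    rm = as.vector(t(draws[, rm_idx, drop = FALSE])),
    tm = as.vector(t(draws[, tm_idx, drop = FALSE])),
    stringsAsFactors = FALSE
  )
  as_paired_series(df, drop_first = FALSE)
}

#' Generate a controlled bias/noise scenario
#'
#' Draws the reference series from `base`'s distribution, then constructs
#' the test series as `tm = rm + bias + noise`. With `bias = 0` and
#' `noise_sd = 0` the test method reproduces the reference exactly, so
#' every interpretable change must classify as interchangeable (the
#' identity oracle).
#'
#' @param base a [tim_design()] object supplying the reference series.
#' @param bias additive systematic offset of the test method (units).
#' @param noise_sd standard deviation of additive zero-mean noise (units).
#' @return a `"paired_series"` object.
#' @examples
#' s <- simulate_biased(tim_design(n_patients = 6, seed = 1), bias = 0.5)
#' @export
simulate_biased <- function(base, bias = 0, noise_sd = 0) {
  stopifnot(inherits(base, "tim_design"), noise_sd >= 0)
  s <- simulate_series(base)
  noise <- if (noise_sd > 0) stats::rnorm(nrow(s), 0, noise_sd) else 0
  s$tm <- s$rm + bias + noise
  s
}
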