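# Independent brute-force classifier used as an oracle.
# Interpretability is tested from the raw interval endpoints; the zone test
# evaluates the two published line equations directly; gray-zone membership
# is decided by dense sampling of the second point's precision interval.
oracle_classify <- function(rm1, tm1, rm2, tm2, rc, n_grid = 2001,
                            symmetric_intercepts = FALSE) {
  lo1 <- rm1 - abs(rm1) * rc; hi1 <- rm1 + abs(rm1) * rc
  lo2 <- rm2 - abs(rm2) * rc; hi2 <- rm2 + abs(rm2) * rc
  overlap <- !(hi1 < lo2 || hi2 < lo1)  # touching counts as overlap
  if (overlap) return("uninterpretable")

  off_up <- (1 + rc) * (rm1 - tm1)
  off_lo <- if (symmetric_intercepts) (1 - rc) * (rm1 - tm1) else off_up
  x_a <- (1 + rc) * tm2 + off_up
  x_b <- (1 - rc) * tm2 + off_lo
  zlo <- min(x_a, x_b); zhi <- max(x_a, x_b)
  if (rm2 >= zlo && rm2 <= zhi) return("interchangeable")

  grid <- seq(lo2, hi2, length.out = n_grid)
  if (any(grid >= zlo & grid <= zhi)) return("gray_zone")
  "noninterchangeable"
}

# Random change quadruples over the positive range the method targets.
random_quadruples <- function(n, lo = 0.5, hi = 8) {
  data.frame(
    rm1 = runif(n, lo, hi), tm1 = runif(n, lo, hi),
    rm2 = runif(n, lo, hi), tm2 = runif(n, lo, hi)
  )
}

# Hand-built series as a long data frame.
long_series <- function(rm, tm, subject = "S1", device = "TM") {
  data.frame(subject = subject, device = device,
             time = seq_along(rm), rm = rm, tm = tm,
             stringsAsFactors = FALSE)
}

# The four didactic changes: all concordant and within +/-30 degrees in
# the legacy views, yet one of each interchangeability category at rc = 0.2.
didactic_changes <- function() {
  data.frame(
    rm1 = c(4, 4, 4, 4), tm1 = c(4, 4, 4, 4),
    rm2 = c(4.1, 7, 10, 13), tm2 = c(4.3, 7, 7, 7)
  )
}
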