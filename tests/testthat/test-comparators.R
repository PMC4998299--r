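test_that("concordance rate counts the quadrants of agreement", {
  expect_equal(concordance_rate(c(1, -1), c(1, -1))$rate, 1)
  expect_equal(concordance_rate(c(1, -1), c(-1, 1))$rate, 0)
  # absolute exclusion zone removes the small change
  r <- concordance_rate(c(0.3, 1, -1), c(0.3, 1, 1), exclusion = 0.5)
  expect_equal(r$rate, 0.5)
  expect_equal(r$n_excluded, 1)
  expect_equal(r$n_used, 2)
  # all excluded: undefined with warning
  expect_warning(r0 <- concordance_rate(0.1, 0.1, exclusion = 1), "undefined")
  expect_true(is.na(r0$rate))
})

test_that("percentage exclusion makes the concordance rate scale-free", {
  set.seed(8)
  drm <- rnorm(200)
  dtm <- drm + rnorm(200, sd = 0.5)
  base <- concordance_rate(drm, dtm, exclusion = 25, exclusion_type = "percent")
  for (k in c(0.01, 3, 1000)) {
    scaled <- concordance_rate(k * drm, k * dtm, exclusion = 25,
                               exclusion_type = "percent")
    expect_equal(scaled$rate, base$rate)
    expect_equal(scaled$n_excluded, base$n_excluded)
  }
})

test_that("polar conversion measures angles from the line of identity", {
  expect_equal(to_polar(1, 1)$angle, 0)
  expect_equal(to_polar(1, 0)$angle, -45)
  expect_equal(to_polar(0, 1)$angle, 45)
  # fold convention: a concordant decrease reads like a concordant increase
  expect_equal(to_polar(-1, -1)$angle, 0)
  expect_equal(to_polar(-1, -1, fold = FALSE)$angle, -180)
  expect_equal(to_polar(3, 4)$radius, 5)
  expect_warning(p0 <- to_polar(0, 0), "zero-length")
  expect_true(is.na(p0$angle))
})

test_that("polar angle properties: identity direction and axis swap", {
  set.seed(12)
  d <- runif(50, 0.01, 10)
  expect_equal(to_polar(d, d)$angle, rep(0, 50))
  drm <- rnorm(50); dtm <- rnorm(50)
  nz <- abs(drm) + abs(dtm) > 0
  expect_equal(to_polar(dtm[nz], drm[nz])$angle, -to_polar(drm[nz], dtm[nz])$angle)
  expect_true(all(abs(to_polar(drm[nz], dtm[nz], fold = FALSE)$angle) <= 180))
})

test_that("polar statistics summarise angular bias and radial limits", {
  p <- data.frame(radius = c(1, 1), angle = c(-10, 10))
  s <- polar_stats(p)
  expect_equal(s$angular_bias, 0)

  p <- data.frame(radius = rep(1, 3), angle = c(0, 10, 20))
  s <- polar_stats(p)
  expect_equal(s$angular_bias, 10)
  expect_equal(s$radial_loa, 1.96 * sd(c(0, 10, 20)))

  # degenerate perfect agreement
  s0 <- polar_stats(data.frame(radius = c(1, 2), angle = c(0, 0)))
  expect_equal(s0$angular_bias, 0)
  expect_equal(s0$radial_loa, 0)

  # the radius exclusion zone removes short vectors first
  s1 <- polar_stats(data.frame(radius = c(0.2, 1, 1), angle = c(90, 0, 10)),
                    exclusion_radius = 0.5)
  expect_equal(s1$n_excluded, 1)
  expect_equal(s1$angular_bias, 5)
  expect_warning(s2 <- polar_stats(data.frame(radius = 1, angle = 0)),
                 "fewer than 2")
  expect_true(is.na(s2$angular_bias))
})

test_that("legacy views cannot separate the four interchangeability categories", {
  d <- didactic_changes()
  cls <- classify_change(d$rm1, d$tm1, d$rm2, d$tm2, rc = 0.20)
  # one change of each category ...
  expect_setequal(as.character(cls), tim_categories())
  # ... yet all four are concordant in the 4-quadrant sense ...
  drm <- d$rm2 - d$rm1
  dtm <- d$tm2 - d$tm1
  expect_equal(concordance_rate(drm, dtm)$rate, 1)
  # ... and all four lie within the +/-30 degree radial limits
  expect_true(all(abs(to_polar(drm, dtm)$angle) <= 30))
})
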