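test_that("precision interval is value +/- |value| * rc", {
  expect_equal(precision_interval(4, 0.05), cbind(lo = 3.8, hi = 4.2))
  expect_equal(precision_interval(2.5, 0.20), cbind(lo = 2.0, hi = 3.0))
  # zero measurement has a zero-width interval; negative values keep lo <= hi
  expect_equal(precision_interval(0, 0.20), cbind(lo = 0, hi = 0))
  iv <- precision_interval(-2, 0.1)
  expect_true(iv[, "lo"] <= iv[, "hi"])
  expect_equal(unname(iv), cbind(-2.2, -1.8), ignore_attr = TRUE)
  expect_error(precision_interval(Inf, 0.05), "finite")
  expect_error(precision_interval(NA_real_, 0.05), "finite")
})

test_that("repeatability coefficient accepts fractions and percents", {
  expect_equal(repeatability_coef(0.05), 0.05)
  expect_equal(repeatability_coef(5), 0.05)
  expect_equal(repeatability_coef(20), 0.2)
  expect_error(repeatability_coef(0), "positive")
  expect_error(repeatability_coef(-0.1), "positive")
  expect_error(repeatability_coef(150), "below 100")
})

test_that("interpretability screen requires disjoint reference intervals", {
  expect_true(is_interpretable(4, 5, rc = 0.05))
  expect_false(is_interpretable(4, 4.2, rc = 0.20))
  expect_false(is_interpretable(3, 3, rc = 0.05))
  # intervals touching at one boundary point count as overlapping:
  # (4 -> 3.8..4.2) and (4.42105.. -> hi1 == lo2) must be uninterpretable
  rm2 <- 4.2 / 0.95  # lo2 = rm2 * (1 - 0.05) == hi1 exactly
  expect_false(is_interpretable(4, rm2, rc = 0.05))
  # just beyond the touch point it becomes interpretable
  expect_true(is_interpretable(4, rm2 + 1e-6, rc = 0.05))
  # symmetric in its arguments
  expect_equal(is_interpretable(c(2, 5), c(5, 2), rc = 0.1),
               c(TRUE, TRUE))
})

test_that("interchangeability lines match the published equations", {
  ln <- interchangeability_lines(3, 3, rc = 0.05)
  expect_equal(unname(ln$upper), c(1.05, 0))
  expect_equal(unname(ln$lower), c(0.95, 0))

  ln <- interchangeability_lines(4, 3, rc = 0.05)
  expect_equal(unname(ln$upper), c(1.05, 1.05))
  expect_equal(unname(ln$lower), c(0.95, 1.05))

  ln <- interchangeability_lines(4, 5, rc = 0.20)
  expect_equal(unname(ln$upper), c(1.2, -1.2))
  expect_equal(unname(ln$lower), c(0.8, -1.2))

  # the symmetric-intercept variant changes only the lower line's offset
  ln2 <- interchangeability_lines(4, 5, rc = 0.20, symmetric_intercepts = TRUE)
  expect_equal(unname(ln2$upper), c(1.2, -1.2))
  expect_equal(unname(ln2$lower), c(0.8, -0.8))
})

test_that("region status locates the second pair against the zone", {
  ln <- interchangeability_lines(4, 3, rc = 0.05)
  # zone at Y = 5 is [0.95*5 + 1.05, 1.05*5 + 1.05] = [5.8, 6.3]
  expect_equal(region_status(6, 5, ln), "inside")
  expect_equal(region_status(8, 5, ln), "outside")
  # precision interval of rm2 = 6.6 is (6.27, 6.93): touches 6.3
  expect_equal(region_status(6.6, 5, ln), "boundary_overlap")
  # points exactly on a line are inside (closed region)
  expect_equal(region_status(6.3, 5, ln), "inside")
  expect_equal(region_status(5.8, 5, ln), "inside")

  ident <- interchangeability_lines(3, 3, rc = 0.05)
  expect_equal(region_status(5, 5, ident), "inside")
})

test_that("two-step classification follows the simplified algorithm", {
  expect_equal(as.character(classify_change(3, 3, 5, 5, rc = 0.05)),
               "interchangeable")
  # overlapping reference intervals: test values never consulted
  expect_equal(as.character(classify_change(4, 4, 4.1, 6, rc = 0.20)),
               "uninterpretable")
  expect_equal(as.character(classify_change(4, 3, 8, 5, rc = 0.05)),
               "noninterchangeable")
  expect_equal(as.character(classify_change(4, 3, 6.6, 5, rc = 0.05)),
               "gray_zone")
  # missing members propagate as NA (excluded), not as a category
  expect_true(is.na(classify_change(4, NA, 6, 5, rc = 0.05)))
  # non-positive measurements are flagged
  expect_warning(classify_change(-1, 1, 3, 3, rc = 0.05), "non-positive")
})

test_that("classification agrees with the brute-force oracle", {
  set.seed(11)
  q <- random_quadruples(2000)
  for (rc in c(0.05, 0.20)) {
    got <- as.character(classify_change(q$rm1, q$tm1, q$rm2, q$tm2, rc = rc))
    want <- mapply(oracle_classify, q$rm1, q$tm1, q$rm2, q$tm2, rc = rc)
    expect_identical(got, unname(want))
  }
  # and under the symmetric-intercept variant
  got <- as.character(classify_change(q$rm1, q$tm1, q$rm2, q$tm2, rc = 0.1,
                                      symmetric_intercepts = TRUE))
  want <- mapply(oracle_classify, q$rm1, q$tm1, q$rm2, q$tm2, rc = 0.1,
                 symmetric_intercepts = TRUE)
  expect_identical(got, unname(want))
})

test_that("identity series classify every interpretable change as interchangeable", {
  set.seed(21)
  for (i in 1:20) {
    v <- runif(10, 0.5, 8)
    cls <- classify_change(v[-10], v[-10], v[-1], v[-1], rc = 0.1)
    interp <- is_interpretable(v[-10], v[-1], rc = 0.1)
    expect_true(all(as.character(cls[interp]) == "interchangeable"))
    expect_true(all(as.character(cls[!interp]) == "uninterpretable"))
  }
})

test_that("uninterpretable set grows monotonically with rc", {
  set.seed(31)
  q <- random_quadruples(500)
  rcs <- c(0.02, 0.05, 0.1, 0.2, 0.4)
  flags <- sapply(rcs, function(rc) !is_interpretable(q$rm1, q$rm2, rc))
  for (j in seq_along(rcs)[-1]) {
    expect_true(all(flags[, j] >= flags[, j - 1]))
  }
})

test_that("classifications are invariant to positive rescaling", {
  set.seed(41)
  q <- random_quadruples(500)
  base <- classify_change(q$rm1, q$tm1, q$rm2, q$tm2, rc = 0.1)
  for (k in c(0.001, 0.37, 10, 1e4)) {
    scaled <- classify_change(k * q$rm1, k * q$tm1, k * q$rm2, k * q$tm2,
                              rc = 0.1)
    expect_identical(scaled, base)
  }
})
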