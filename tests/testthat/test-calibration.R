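test_that("slope calibration follows the reference concentration anchor", {
  s <- calibrate_slopes(calibration_spec())
  expect_equal(s[["high"]], -0.5 / 79)
  expect_equal(s[["intermediate"]] / s[["high"]], 0.5)
  expect_equal(s[["low"]] / s[["high"]], 0.05)
  expect_identical(s[["none"]], 0)

  zero <- calibration_spec(category_ratio = c(high = 0, intermediate = 0,
                                              low = 0, none = 0))
  expect_true(all(calibrate_slopes(zero) == 0))

  expect_error(calibration_spec(reference_nl_from = 15, reference_nl_to = 15),
               "degenerate")
  expect_error(calibration_spec(reference_nl_to = 100), "smaller")
})

test_that("high-category quality function reproduces the reference QALY gain", {
  g <- list(id = 3L, vo_category = "high", n_patients = 405124L)
  qf <- build_quality_function(g, calibration_spec(), max_sites = 150)
  expect_equal(evaluate_quality_qaly(qf, 94), 0)
  expect_equal(evaluate_quality_qaly(qf, 15) - evaluate_quality_qaly(qf, 94),
               0.5)
  # strictly decreasing in the location count
  vals <- evaluate_quality_qaly(qf, 1:150)
  expect_true(all(diff(vals) < 0))
})

test_that("no-volume-outcome groups have identically zero quality", {
  g <- list(id = 4L, vo_category = "none", n_patients = 17445L)
  qf <- build_quality_function(g, calibration_spec(), max_sites = 150)
  expect_true(all(evaluate_quality_qaly(qf, 1:150) == 0))
  expect_true(all(evaluate_quality_eur(g, qf, 1:150, eq = 50000) == 0))
})

test_that("monetized quality follows the segment formula and scales linearly", {
  g <- list(id = 1L, vo_category = "high", n_patients = 100L)
  qf <- structure(data.frame(nl_lo = 1L, nl_hi = 50L,
                             slope = -0.005, intercept = 0.47),
                  class = c("quality_function", "data.frame"),
                  group_id = 1L, vo_category = "high")
  expect_equal(evaluate_quality_eur(g, qf, 14, eq = 50000), 2e6)
  # linear in EQ and in NP_d
  expect_equal(evaluate_quality_eur(g, qf, 14, eq = 100000), 4e6)
  g2 <- g; g2$n_patients <- 200L
  expect_equal(evaluate_quality_eur(g2, qf, 14, eq = 50000), 4e6)
  expect_error(evaluate_quality_qaly(qf, 51), "outside")
})

test_that("category ordering of gains holds below the baseline", {
  spec <- calibration_spec()
  gain <- vapply(c("high", "intermediate", "low", "none"), function(cc) {
    qf <- build_quality_function(list(id = 1L, vo_category = cc), spec, 150)
    evaluate_quality_qaly(qf, 20)
  }, numeric(1))
  expect_true(gain[["high"]] >= gain[["intermediate"]])
  expect_true(gain[["intermediate"]] >= gain[["low"]])
  expect_true(gain[["low"]] >= gain[["none"]])
  expect_identical(gain[["none"]], 0)
})

test_that("piecewise builds are continuous at segment knots", {
  spec <- calibration_spec()
  for (shape in c("linear", "convex")) {
    qf <- build_quality_function(list(id = 1L, vo_category = "high"),
                                 spec, 150, shape = shape)
    for (k in seq_len(nrow(qf) - 1)) {
      x <- qf$nl_hi[k]
      v1 <- qf$slope[k] * x + qf$intercept[k]
      v2 <- qf$slope[k + 1] * x + qf$intercept[k + 1]
      expect_lt(abs(v1 - v2), 1e-9)
    }
  }
  # convex build still anchors the reference gain and zero baseline
  qf <- build_quality_function(list(id = 1L, vo_category = "high"),
                               spec, 150, shape = "convex")
  expect_equal(evaluate_quality_qaly(qf, 94), 0)
  expect_equal(evaluate_quality_qaly(qf, 15), 0.5)
  expect_gt(evaluate_quality_qaly(qf, 1), 0.5 + 0.5 / 79)
})
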