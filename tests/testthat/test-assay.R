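test_that("ssDNA percentage follows the qPCR closed form", {
  expect_identical(ssdnaPercentage(0), 100)
  expect_equal(ssdnaPercentage(1), 100 / 1.5, tolerance = 1e-9)
  expect_equal(ssdnaPercentage(3), 100 / 4.5, tolerance = 1e-9)
  ## strictly decreasing, limit 0
  x <- seq(-1, 20, by = 0.25)
  y <- suppressWarnings(ssdnaPercentage(x))
  expect_true(all(diff(y) < 0))
  expect_lt(ssdnaPercentage(30), 1e-6)
  expect_warning(ssdnaPercentage(-0.5), "negative")
  expect_error(ssdnaPercentage(NA_real_), "finite")
  expect_error(ssdnaPercentage(Inf), "finite")
})

test_that("control normalization rescales to control mean one", {
  expect_equal(normalizeToControl(c(2, 4), 2), c(1, 2))
  ctrl <- c(3, 3, 3)
  expect_equal(normalizeToControl(ctrl, mean(ctrl)), rep(1, 3))
  expect_identical(normalizeToControl(numeric(0), 2), numeric(0))
  ## idempotent once the control mean is 1
  v <- normalizeToControl(c(2, 8), 4)
  expect_equal(normalizeToControl(v, 1), v)
  expect_error(normalizeToControl(1:3, 0), "positive")
  expect_error(normalizeToControl(1:3, -2), "positive")
})
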