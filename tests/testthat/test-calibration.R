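test_that("calibrants are assigned to the nearest peak within the window", {
  stds <- internalStandards(c("RfffR", "ACTH"), c(1042.276, 2465.199))
  pk <- peakList(c(1042.281, 2465.210, 1800.0), c(100, 50, 10))
  asg <- matchCalibrants(pk, stds, window = 0.5)
  expect_equal(nrow(asg), 2L)
  expect_equal(asg$peakIndex, c(1L, 2L))
  expect_equal(asg$deltaDa, c(0.005, 0.011), tolerance = 1e-9)

  none <- matchCalibrants(peakList(c(500, 600)), stds, window = 0.5)
  expect_equal(nrow(none), 0L)
})

test_that("equidistant calibrant candidates resolve to the more intense peak", {
  stds <- internalStandards("X", 1000.0)
  pk <- peakList(c(999.9, 1000.1), c(5, 50))
  asg <- matchCalibrants(pk, stds, window = 0.5)
  expect_equal(asg$peakIndex, 2L)
})

test_that("each peak serves at most one standard; nearest standard wins", {
  stds <- internalStandards(c("S1", "S2"), c(1000.00, 1000.30))
  pk <- peakList(c(1000.05, 1000.28), c(10, 10))
  asg <- matchCalibrants(pk, stds, window = 0.5)
  expect_equal(nrow(asg), 2L)
  expect_equal(asg$peakIndex[asg$name == "S1"], 1L)
  expect_equal(asg$peakIndex[asg$name == "S2"], 2L)
})

test_that("affine fits recover exact constructions", {
  # identity
  pairs <- data.frame(theoreticalMh = c(1042.276, 2465.199),
                      observedMz = c(1042.276, 2465.199))
  m <- fitCalibration(pairs)
  expect_equal(calibrationSlope(m), 1, tolerance = 1e-12)
  expect_equal(calibrationIntercept(m), 0, tolerance = 1e-9)

  # constant offset
  pairs$observedMz <- pairs$theoreticalMh + 0.05
  m <- fitCalibration(pairs)
  expect_equal(calibrationSlope(m), 1, tolerance = 1e-10)
  expect_equal(calibrationIntercept(m), -0.05, tolerance = 1e-8)

  # two-point affine is exact
  a <- 1.0001; b <- -0.02
  pairs$observedMz <- (pairs$theoreticalMh - b) / a
  m <- fitCalibration(pairs)
  expect_equal(calibrationSlope(m), a, tolerance = 1e-10)
  expect_equal(calibrationIntercept(m), b, tolerance = 1e-7)
  expect_true(all(abs(calibrationResiduals(m)) < 1e-6))
})

test_that("single-calibrant fits degrade to a constant offset", {
  m <- fitCalibration(data.frame(theoreticalMh = 2465.199,
                                 observedMz = 2465.230))
  expect_equal(calibrationSlope(m), 1)
  expect_equal(calibrationIntercept(m), -0.031, tolerance = 1e-9)
})

test_that("degenerate calibrant sets are rejected", {
  expect_error(fitCalibration(data.frame(theoreticalMh = numeric(),
                                         observedMz = numeric())), "at least one")
  expect_error(fitCalibration(NULL), "at least one")
  expect_error(fitCalibration(data.frame(theoreticalMh = c(1000, 2000),
                                         observedMz = c(1500, 1500))),
               "identical observed")
})

test_that("applying a model transforms m/z only and flags the list", {
  pk <- peakList(c(1042.326, 2465.249), c(7, 9), sourceId = "s")
  ident <- fitCalibration(data.frame(theoreticalMh = c(1000, 2000),
                                     observedMz = c(1000, 2000)))
  out <- applyCalibration(pk, ident)
  expect_equal(mz(out), mz(pk))
  expect_true(isCalibrated(out))
  expect_false(isCalibrated(pk))          # original untouched

  shift <- fitCalibration(data.frame(theoreticalMh = c(1000, 2000),
                                     observedMz = c(1000.05, 2000.05)))
  out2 <- applyCalibration(pk, shift)
  expect_equal(mz(out2)[1], 1042.276, tolerance = 1e-6)
  expect_equal(intensity(out2), intensity(pk))
  expect_error(applyCalibration(out2, shift), "already calibrated")

  empty <- applyCalibration(peakList(numeric()), shift)
  expect_equal(length(empty), 0L)
  expect_true(isCalibrated(empty))
})

test_that("a fitted model round-trips the calibrant peaks within its residuals", {
  set.seed(5)
  stds <- defaultCalibrants()
  obs <- (stds$theoreticalMh - (-0.03)) / 1.0001 *
    (1 + rnorm(nrow(stds), 0, 5e-6))
  pk <- peakList(obs, rep(10, length(obs)))
  asg <- matchCalibrants(pk, stds, window = 0.5)
  m <- fitCalibration(asg)
  corrected <- mz(applyCalibration(pk, m))
  errPpm <- 1e6 * (corrected - stds$theoreticalMh) / stds$theoreticalMh
  expect_lte(max(abs(errPpm)), max(abs(calibrationResiduals(m))) + 1e-9)
})

test_that("known affine distortions are recovered under ppm noise", {
  res <- t(vapply(1:50, calibrationReplicate, numeric(3),
                  a = 1.0001, b = -0.02, noisePpm = 5))
  expect_true(all(res[, "n"] == 6))
  okA <- res[, "aErr"] <= 5e-5
  okB <- res[, "bErr"] <= 0.02
  expect_gte(mean(okA & okB), 0.9)
  expect_lt(median(res[, "aErr"]), 1e-5)
  expect_lt(median(res[, "bErr"]), 0.01)
})

test_that("calibration preserves peak count and intensities", {
  set.seed(9)
  pk <- peakList(runif(30, 800, 3000), runif(30, 1, 100))
  m <- fitCalibration(data.frame(theoreticalMh = c(1000, 2500),
                                 observedMz = c(1000.1, 2500.2)))
  out <- applyCalibration(pk, m)
  expect_equal(length(out), length(pk))
  expect_equal(intensity(out), intensity(pk))
})
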