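## a complex bin carrying a real waveform on a rotated axis
rotatedBin <- function(wave, phi = 0.7, gain = 1, center = 2 + 1i) {
  center + gain * exp(1i * phi) * wave
}

test_that("weights are power-proportional and polarities sign-correct", {
  w0 <- sin(2 * pi * 0.25 * (0:339) / 17)
  b1 <- rotatedBin(w0)
  x <- rangeBinMatrix(rbind(b1, b1), bins = c(24L, 25L))
  w <- computeWeightsAndPolarity(x)
  expect_equal(w@weights, c(0.5, 0.5))
  expect_equal(w@polarity, c(1, 1))

  xi <- rangeBinMatrix(rbind(b1, -b1), bins = c(24L, 25L))
  wi <- computeWeightsAndPolarity(xi, referenceBin = 24L)
  expect_equal(wi@weights, c(0.5, 0.5))
  expect_equal(wi@polarity, c(1, -1))

  ## powers 4:1 -> weights 0.8 / 0.2
  xp <- rangeBinMatrix(rbind(rotatedBin(2 * w0), rotatedBin(w0, phi = 2.1)),
                       bins = c(24L, 25L))
  wp <- computeWeightsAndPolarity(xp, referenceBin = 24L)
  expect_equal(wp@weights, c(0.8, 0.2), tolerance = 1e-10)

  expect_warning(wz <- computeWeightsAndPolarity(
    rangeBinMatrix(matrix(0 + 0i, 3, 50))), "uniform")
  expect_equal(wz@weights, rep(1 / 3, 3))
  expect_true(all(wz@polarity == 1))
})

test_that("a single unit-weight bin passes through the average unchanged", {
  w0 <- cos(2 * pi * 0.2 * (0:199) / 17)
  x <- rangeBinMatrix(matrix(rotatedBin(w0, phi = 0), 1), bins = 25L)
  w <- computeWeightsAndPolarity(x)
  out <- signalSamples(rangeBinWeightedAverage(x, w))
  expect_equal(out, w0 - mean(w0), tolerance = 1e-10)
})

test_that("coherent averaging gains sqrt(N) in SNR", {
  set.seed(21)
  n <- 17 * 90
  s <- sin(2 * pi * 0.25 * (0:(n - 1)) / 17)
  mk <- function(sign = 1) rotatedBin(sign * s + rnorm(n, 0, 0.6),
                                      phi = runif(1, 0, pi))
  bins <- t(vapply(1:11, function(k) mk(), complex(n)))
  x <- rangeBinMatrix(bins)
  w <- computeWeightsAndPolarity(x)
  snr <- function(v) { f <- lm(v ~ s); sd(fitted(f)) / sd(resid(f)) }
  perBin <- projectBins(x, w)
  gain <- snr(signalSamples(rangeBinWeightedAverage(x, w))) /
    mean(apply(perBin, 1, snr))
  expect_lt(abs(gain - sqrt(11)) / sqrt(11), 0.2)

  ## an uncorrected inverted bin degrades the average
  binsInv <- bins
  binsInv[4, ] <- rotatedBin(-s + rnorm(n, 0, 0.6), phi = 1.1)
  xi <- rangeBinMatrix(binsInv)
  wc <- computeWeightsAndPolarity(xi)
  wu <- new("BinWeights", bins = wc@bins, weights = wc@weights,
            polarity = abs(wc@polarity), axes = wc@axes,
            centers = wc@centers, referenceBin = wc@referenceBin)
  ## force the inverted bin to +1 regardless of the estimated polarity
  corrected <- snr(signalSamples(rangeBinWeightedAverage(xi, wc)))
  uncorrected <- snr(signalSamples(rangeBinWeightedAverage(xi, wu)))
  expect_gt(corrected, uncorrected)
})

test_that("polarity correction is idempotent", {
  set.seed(22)
  n <- 17 * 60
  s <- sin(2 * pi * 0.25 * (0:(n - 1)) / 17)
  bins <- rbind(rotatedBin(s + rnorm(n, 0, 0.2)),
                rotatedBin(-s + rnorm(n, 0, 0.2), phi = 1.3),
                rotatedBin(s + rnorm(n, 0, 0.2), phi = 2.4))
  x <- rangeBinMatrix(bins, bins = 24:26)
  w1 <- computeWeightsAndPolarity(x, referenceBin = 24L)
  corrected <- projectBins(x, w1) * w1@polarity
  iref <- match(24L, w1@bins)
  pol2 <- as.numeric(sign(corrected %*% corrected[iref, ]))
  expect_equal(pol2, rep(1, 3))
})

test_that("the moving average is causal, length-preserving and smoothing", {
  v <- c(1, 2, 3, 4, 5)
  expect_equal(movingAverage(v, 1), v)                      # identity
  expect_equal(movingAverage(rep(7, 10), 4), rep(7, 10))    # constant
  expect_equal(movingAverage(v, 3), c(1, 1.5, 2, 3, 4))     # partial start
  expect_error(movingAverage(v, 6), "exceeds")
  set.seed(23)
  z <- rnorm(20000)
  zm <- movingAverage(z, 17)
  expect_lt(abs(var(zm[17:20000]) * 17 - 1), 0.15)  # variance / window
  ## centred variant keeps the mean
  expect_equal(mean(movingAverage(z, 17, sides = "centered")), mean(z),
               tolerance = 1e-2)
})

test_that("breathing-rate estimation finds the spectral peak or reports 0", {
  t <- (0:(17 * 70 - 1)) / 17
  expect_equal(estimateBreathingRate(sin(2 * pi * 0.25 * t), windowS = 70,
                                     rate = 17), 15, tolerance = 0.05)
  expect_equal(estimateBreathingRate(rep(0, 1190), windowS = 30, rate = 17),
               0)
  set.seed(24)
  x <- sin(2 * pi * 0.2 * t) + rnorm(length(t), 0, 0.2)
  bpm <- estimateBreathingRate(x, windowS = 70, rate = 17)
  expect_lt(abs(bpm - 12), 60 * 17 / 2^ceiling(log2(length(t) * 4)) + 1e-9)
  expect_error(estimateBreathingRate(x, windowS = 2, rate = 17),
               "window too short")
  expect_error(estimateBreathingRate(x[1:100], windowS = 30, rate = 17),
               "exceeds")
  expect_true(is.na(dominantFrequency(rep(1, 100), rate = 17)))
})
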