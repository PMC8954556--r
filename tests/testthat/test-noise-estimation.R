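## helper: an estimator that predicts exactly zero (weights and output
## statistics all zero), for closed-form MSE checks
zeroModel <- function(referenceBins, targetBins) {
  nIn <- 2L * length(referenceBins); nOut <- 2L * length(targetBins)
  arch <- new("EstimatorArchitecture", nInputs = nIn, hidden = c(4L, 4L),
              nOutputs = nOut)
  layers <- list(list(W = matrix(0, nIn, 4), b = rep(0, 4)),
                 list(W = matrix(0, 4, 4), b = rep(0, 4)),
                 list(W = matrix(0, 4, nOut), b = rep(0, nOut)))
  new("NoiseEstimatorModel", architecture = arch, weights = layers,
      normalization = list(xMean = rep(0, nIn), xSd = rep(1, nIn),
                           yMean = rep(0, nOut), ySd = rep(1, nOut)),
      referenceBins = as.integer(referenceBins),
      targetBins = as.integer(targetBins),
      trainingMse = 0, validationMse = 0, testMse = 0, converged = TRUE,
      control = list(), seed = 0L)
}

randomMatrix <- function(nBins = 128L, n = 1000L, seed = 1) {
  set.seed(seed)
  rangeBinMatrix(matrix(complex(real = rnorm(nBins * n),
                                imaginary = rnorm(nBins * n)), nBins, n))
}

test_that("training sets have one row per sample and interleaved channels", {
  x <- randomMatrix()
  refs <- c(15L, 18L, 123L, 45L, 60L, 85L, 105L)
  ds1 <- buildTrainingSet(x, refs, 25L)
  expect_equal(dim(ds1$inputs), c(1000L, 14L))
  expect_equal(dim(ds1$labels), c(1000L, 2L))
  ds11 <- buildTrainingSet(x, refs, 20:30)
  expect_equal(dim(ds11$labels), c(1000L, 22L))
  ## interleaving: columns 1,2 are Re/Im of the first reference bin
  expect_equal(ds1$inputs[, 1], Re(binValues(x)[15, ]))
  expect_equal(ds1$inputs[, 2], Im(binValues(x)[15, ]))
  z <- rangeBinMatrix(matrix(0 + 0i, 128, 50))
  dz <- buildTrainingSet(z, refs, 25L)
  expect_true(all(dz$inputs == 0) && all(dz$labels == 0))
  expect_error(buildTrainingSet(x, c(15L, 25L), 20:30), "overlap")
})

test_that("architecture presets instantiate the canonical layer widths", {
  sb <- sbArchitecture()
  expect_equal(sb@nInputs, 14L)
  expect_equal(sb@hidden, c(56L, 28L))
  expect_equal(sb@nOutputs, 2L)
  rb <- rbArchitecture()
  expect_equal(rb@nInputs, 14L)
  expect_equal(rb@hidden, c(126L, 22L))
  expect_equal(rb@nOutputs, 22L)
  expect_error(trainingSplit(0.5, 0.3, 0.3))
  expect_equal(sum(trainingSplit()@fractions), 1)
})

test_that("zero labels train to a near-zero predictor", {
  set.seed(2)
  X <- matrix(rnorm(300 * 14), 300, 14)
  Y <- matrix(0, 300, 2)
  m <- trainEstimator(X, Y, sbArchitecture(), seed = 3L,
                      control = list(maxEpochs = 400L, optimizer = "lbfgs"))
  expect_lt(m@trainingMse, 1e-6)
  expect_true(m@converged)
})

test_that("a noiseless linear mix is fitted to the least-squares floor", {
  set.seed(4)
  X <- matrix(rnorm(2000 * 14), 2000, 14)
  B <- matrix(rnorm(14 * 2), 14, 2)
  Y <- X %*% B
  m <- trainEstimator(X, Y, sbArchitecture(), seed = 5L,
                      control = list(maxEpochs = 1200L,
                                     optimizer = "lbfgs"))
  ## the exact linear least-squares residual is zero here; the network must
  ## come within 1e-4 of the label variance on held-out rows
  expect_lt(m@testMse, 1e-4 * 2 * mean(Y^2))
})

test_that("training is deterministic for a fixed seed", {
  set.seed(6)
  X <- matrix(rnorm(200 * 14), 200, 14)
  Y <- X %*% matrix(rnorm(28), 14, 2) + rnorm(400, 0, 0.1)
  m1 <- trainEstimator(X, Y, sbArchitecture(), seed = 9L,
                       control = list(maxEpochs = 100L))
  m2 <- trainEstimator(X, Y, sbArchitecture(), seed = 9L,
                       control = list(maxEpochs = 100L))
  expect_identical(m1@weights, m2@weights)
  expect_identical(m1@testMse, m2@testMse)
  expect_error(trainEstimator(X * NA, Y, sbArchitecture()), "non-finite")
})

test_that("the range-bin estimator beats the 10% normalized-MSE floor", {
  prof <- fixtureRbProfile()
  sc <- fixtureTrainScene()
  tb <- binValues(restrictBins(sc@truth@interferenceOnly, 20:30))
  intfPow <- mean(Mod(tb - rowMeans(tb))^2)
  expect_lt(prof@model@testMse / intfPow, 0.1)
  ## applying the model to its own training recording reproduces the
  ## recorded split MSEs (overall MSE = sample-weighted mean of the splits)
  est <- estimateNoise(prof@model, sc@scene)
  allMse <- mean(Mod(binValues(est) -
                       binValues(restrictBins(sc@scene, 20:30)))^2)
  n <- sampleCount(sc@scene)
  nTrain <- floor(0.7 * n); nVal <- floor(0.15 * n)
  nTest <- n - nTrain - nVal
  expected <- (nTrain * prof@model@trainingMse +
                 nVal * prof@model@validationMse +
                 nTest * prof@model@testMse) / n
  expect_equal(allMse, expected, tolerance = 1e-8)
})

test_that("noise estimates are causal and shape-preserving", {
  x <- randomMatrix(n = 400L, seed = 7)
  m <- zeroModel(c(15L, 18L, 123L), c(24L, 25L))
  est <- estimateNoise(m, x)
  expect_equal(dim(binValues(est)), c(2L, 400L))
  expect_true(all(binValues(est) == 0))      # zero model -> zero estimate
  ## causality: a truncated recording yields the identical prefix
  prof <- fixtureRbProfile()
  sc <- fixtureTrainScene()
  full <- estimateNoise(prof@model, sc@scene)
  cut <- rangeBinMatrix(binValues(sc@scene)[, 1:100], rate = 17,
                        bins = binIndices(sc@scene))
  expect_equal(binValues(estimateNoise(prof@model, cut)),
               binValues(full)[, 1:100])
  expect_error(estimateNoise(prof@model, restrictBins(sc@scene, 1:10)),
               "not present")
})

test_that("denoising removes most interference and spares breathing", {
  prof <- fixtureRbProfile()
  ## residual power on an interference-only recording
  cfg <- fixtureCfg(120, seed = 311L)
  sc <- composeScene(cfg, generateIdleTrace(120), speedProfile(120, 1))
  den <- denoise(prof@model, sc@scene)
  tb <- binValues(restrictBins(sc@truth@interferenceOnly, 20:30))
  intfPow <- mean(Mod(tb - rowMeans(tb))^2)
  dv <- binValues(den)
  residPow <- mean(Mod(dv - rowMeans(dv))^2)
  expect_lt(residPow, 0.2 * intfPow)

  ## breathing-only recording through a floor-trained model: low distortion
  cfgQ <- fixtureCfg(120, seed = 312L)
  quiet <- composeScene(cfgQ, generateIdleTrace(120), NULL)
  mFloor <- trainEstimatorFromRecording(quiet@scene, prof@referenceBins,
                                        20:30, arch = "rb", seed = 8L,
                                        control = list(maxEpochs = 300L))
  cfgB <- fixtureCfg(120, seed = 313L)
  breathing <- composeScene(cfgB, generateSinusoidTrace(0.25, 4, 120), NULL)
  denB <- denoise(mFloor, breathing@scene)
  inB <- restrictBins(breathing@scene, 20:30)
  dist <- sqrt(mean(Mod(binValues(denB) + rowMeans(binValues(inB)) -
                          binValues(inB))^2) /
                 mean(Mod(binValues(inB))^2))
  expect_lt(dist, 0.1)

  ## combined scene: denoising raises correlation with the clean target
  cfgC <- fixtureCfg(120, seed = 314L)
  comb <- composeScene(cfgC, generateSinusoidTrace(0.25, 4, 120),
                       speedProfile(120, 1))
  denC <- denoise(prof@model, comb@scene)
  clean <- Re(binValues(comb@truth@cleanTarget)[6, ])
  raw <- Re(binValues(restrictBins(comb@scene, 20:30))[6, ])
  dn <- Re(binValues(denC)[6, ])
  expect_gt(abs(cor(dn, clean)), abs(cor(raw, clean)))
})

test_that("MSE evaluation matches its closed forms", {
  x <- randomMatrix(n = 200L, seed = 10)
  m <- zeroModel(c(15L, 18L, 123L), c(24L, 25L))
  truth <- matrix(0 + 0i, 2, 200)
  ev <- evaluateMse(m, x, truth)           # estimate == truth -> 0
  expect_equal(ev$pooled, 0)
  cshift <- matrix(3 - 4i, 2, 200)         # constant offset -> |c|^2
  ev2 <- evaluateMse(m, x, cshift)
  expect_equal(ev2$pooled, 25)
  expect_equal(unname(ev2$perBin), c(25, 25))
  expect_equal(ev2$pooled, mean(ev2$perBin))  # pooled = mean of per-bin
  expect_error(evaluateMse(m, x, matrix(0 + 0i, 2, 100)), "dimensions")
})
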