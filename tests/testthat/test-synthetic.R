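test_that("sinusoid traces follow the phantom pattern", {
  tr <- generateSinusoidTrace(0.25, 4, 70, 17)
  expect_equal(sampleCount(tr), 1190L)
  expect_equal(diff(range(displacement(tr))), 8, tolerance = 1e-12)
  expect_true(all(classLabels(tr) == "free_breathing"))
  ## independent oracle: discrete Fourier transform of the emitted samples
  d <- displacement(tr)
  P <- Mod(fft(d - mean(d)))^2
  f <- (seq_along(d) - 1) / length(d) * 17
  peak <- f[f <= 8.5][which.max(P[f <= 8.5])]
  expect_lt(abs(peak - 0.25), 17 / length(d))   # within one resolution cell
})

test_that("zero-amplitude traces are idle and labelled no_breathing", {
  tr <- generateSinusoidTrace(0.4, 0, 10, 17)
  expect_true(all(displacement(tr) == 0))
  expect_true(all(classLabels(tr) == "no_breathing"))
  expect_identical(displacement(generateIdleTrace(10)), rep(0, 170))
})

test_that("sinusoid preconditions are enforced", {
  expect_error(generateSinusoidTrace(9, 4, 10, 17), "aliasing")
  expect_error(generateSinusoidTrace(0.25, -1, 10, 17), "amplitude")
  expect_error(generateSinusoidTrace(0.25, 4, 0, 17), "duration")
})

test_that("DIBH traces cycle through all maneuver phases", {
  tr <- generateDibhTrace(4, 12, 20, 0.25, duration = 112, rate = 17)
  expect_equal(sampleCount(tr), 1904L)
  expect_setequal(unique(classLabels(tr)),
                  c("free_breathing", "deep_inspiration", "breath_hold"))
  d <- displacement(tr); lab <- classLabels(tr)
  ## hold plateau: mean-removed excursion is far below free breathing
  rms <- function(v) sqrt(mean((v - mean(v))^2))
  expect_lt(rms(d[lab == "breath_hold"]), rms(d[lab == "free_breathing"]))
  ## peak-to-peak type invariant, per contiguous segment
  expect_lt(max(abs(diff(range(d[lab == "breath_hold"])))), 2)
  ## hold sits at the inhaled plateau
  expect_gt(mean(d[lab == "breath_hold"]), 11)
})

test_that("degenerate and invalid DIBH parameters are handled", {
  tr0 <- generateDibhTrace(4, 12, 0, 0.25, duration = 60)
  expect_false("breath_hold" %in% classLabels(tr0))
  expect_error(generateDibhTrace(12, 4, 20, 0.25, duration = 60),
               "deepAmp > baseAmp")
  expect_error(generateDibhTrace(4, 12, 80, 0.25, duration = 60),
               "smaller than duration")
})

test_that("trace concatenation preserves samples and labels", {
  tr <- concatTraces(generateIdleTrace(10),
                     generateSinusoidTrace(0.25, 4, 10))
  expect_equal(sampleCount(tr), 340L)
  expect_equal(classLabels(tr)[1:170], rep("no_breathing", 170))
})

test_that("parked-gantry interference is only the noise floor", {
  cfg <- fixtureCfg(60, seed = 301L)
  x <- generateGantryInterference(cfg, speedProfile(60, 0))
  pw <- mean(Mod(binValues(x))^2)
  expect_lt(abs(pw - cfg@noiseFloorPower) / cfg@noiseFloorPower, 0.05)
})

test_that("interference power in target bins matches the configured ratio", {
  cfg <- fixtureCfg(120, seed = 302L)
  sp <- speedProfile(c(40, 20, 60), c(1, 0, 0.5))
  x <- generateGantryInterference(cfg, sp)
  speed <- rep(sp$speed, sp$duration * 17)
  tb <- binValues(restrictBins(x, binIndices(cfg)))[, speed > 0]
  pw <- mean(Mod(tb - rowMeans(tb))^2)
  expect_lt(abs(pw - 5 * referenceBreathingPower(cfg)) /
              (5 * referenceBreathingPower(cfg)), 0.1)
  expect_error(generateGantryInterference(cfg, NULL), "empty")
})

test_that("interference is correlated between target and reference bins", {
  cfg <- fixtureCfg(120, seed = 303L)
  x <- generateGantryInterference(cfg, speedProfile(120, 1))
  v <- binValues(x)
  tgt <- v[25, ]
  ## complex correlation magnitude against the best reference bin
  rho <- vapply(cfg@referenceBins, function(b) {
    r <- v[b, ]
    Mod(mean((tgt - mean(tgt)) * Conj(r - mean(r)))) /
      sqrt(mean(Mod(tgt - mean(tgt))^2) * mean(Mod(r - mean(r))^2))
  }, numeric(1))
  expect_gt(max(rho), 0.3)
})

test_that("reference bins linearly predict target-bin interference", {
  cfg <- fixtureCfg(120, seed = 304L)
  x <- generateGantryInterference(cfg, speedProfile(120, 1))
  ds <- buildTrainingSet(x, cfg@referenceBins, 25L)
  fit <- lm(ds$labels[, 1] ~ ds$inputs)
  expect_gt(summary(fit)$r.squared, 0.5)
})

test_that("target projection follows the bin response model", {
  cfg <- fixtureCfg(20, seed = 305L)
  idle <- generateIdleTrace(20)
  x <- projectTarget(idle, cfg)
  v <- binValues(x)
  for (k in seq_along(cfg@targetBins))     # static target: constant phasor
    expect_true(all(v[cfg@targetBins[k], ] == cfg@targetGains[k]))
  expect_true(all(v[-cfg@targetBins, ] == 0))

  tr <- generateSinusoidTrace(0.25, 4, 20)
  v <- binValues(projectTarget(tr, cfg))
  doms <- vapply(cfg@targetBins, function(b) {
    dominantFrequency(Re(v[b, ] - mean(v[b, ])), rate = 17)
  }, numeric(1))
  expect_true(all(abs(doms - 0.25) < 0.02))   # all bins share the rate
})

test_that("full-carrier phase excursion matches the closed form", {
  cfg <- fixtureCfg(20, seed = 306L, phaseGain = 1)
  tr <- generateSinusoidTrace(0.25, 4, 20)
  v <- binValues(projectTarget(tr, cfg))
  k <- which(cfg@couplingSlopes > 0)[1]
  ph <- Arg(v[cfg@targetBins[k], ] / cfg@targetGains[k])
  expect_equal(diff(range(ph)), 2 * 4 * pi * 0.004 / cfg@wavelength,
               tolerance = 1e-10)
})

test_that("scene composition is deterministic and exactly additive", {
  cfg <- fixtureCfg(30, seed = 307L)
  tr <- generateSinusoidTrace(0.25, 4, 30)
  sp <- speedProfile(30, 0.8)
  s1 <- composeScene(cfg, tr, sp)
  s2 <- composeScene(cfg, tr, sp)
  expect_identical(binValues(s1@scene), binValues(s2@scene))
  recon <- binValues(restrictBins(s1@scene, binIndices(cfg))) -
    binValues(restrictBins(s1@truth@interferenceOnly, binIndices(cfg))) -
    binValues(restrictBins(s1@truth@thermalNoise, binIndices(cfg)))
  expect_equal(recon, binValues(s1@truth@cleanTarget), tolerance = 1e-12)
  expect_error(composeScene(cfg, generateSinusoidTrace(0.25, 4, 20), sp),
               "duration")
})

test_that("trace invariants are enforced by the class validity", {
  expect_error(displacementTrace(c(1, 0), labels = c("no_breathing",
                                                     "no_breathing")),
               "identically zero")
  expect_error(displacementTrace(1:3, labels = c("a", "b", "c")),
               "unknown breathing class")
})
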