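test_that("windowed power matches its closed forms", {
  expect_true(all(powerValues(windowedPower(rep(5, 200), 68)) == 0))
  t <- (0:339) / 17
  p1 <- powerValues(windowedPower(sin(2 * pi * 0.25 * t), 68))
  expect_equal(p1[1], 0.5, tolerance = 1e-12)      # unit sinusoid, 1 period
  p4 <- powerValues(windowedPower(4 * sin(2 * pi * 0.25 * t), 68))
  expect_equal(p4[1], 8, tolerance = 1e-12)        # A^2 / 2 with A = 4 mm
  expect_length(p4, 340 - 68 + 1)
  expect_error(windowedPower(1:10, 68), "exceeds")
})

test_that("majority window labels reduce the truth track", {
  lab <- c(rep("no_breathing", 10), rep("free_breathing", 6))
  wl <- windowMajorityLabels(lab, 8)
  expect_equal(wl[1], "no_breathing")
  expect_equal(wl[9], "free_breathing")   # 2 none + 6 free in window 9
  expect_length(wl, 9)
})

test_that("k-means thresholds separate well-spaced power masses", {
  p <- rep(c(0.001, 0.1, 1, 10), each = 50)
  m <- fitThresholds(p, seed = 2L)
  thr <- classifierThresholds(m)
  expect_true(thr[1] > 0.001 && thr[1] < 0.1)
  expect_true(thr[2] > 0.1 && thr[2] < 1)
  expect_true(thr[3] > 1 && thr[3] < 10)
  m2 <- fitThresholds(p, seed = 2L)
  expect_identical(thr, classifierThresholds(m2))  # determinism
  expect_error(fitThresholds(rep(c(1, 2, 3), 10)), "distinct")
})

test_that("fitted thresholds track the accuracy-optimal split points", {
  set.seed(31)
  meanlog <- c(-6, -2.3, 0.4, 2.5)
  truth <- rep(1:4, each = 400)
  p <- exp(rnorm(1600, meanlog[truth], 0.35))
  m <- fitThresholds(p, seed = 3L)
  lthr <- log(classifierThresholds(m) + m@logEpsilon)
  ## oracle: brute-force 1-D threshold search maximizing pairwise accuracy
  for (k in 1:3) {
    sel <- truth %in% c(k, k + 1L)
    lp <- sort(log(p[sel]))
    cand <- (lp[-1] + lp[-length(lp)]) / 2
    accAt <- vapply(cand, function(th)
      mean((log(p[sel]) >= th) == (truth[sel] == k + 1L)), numeric(1))
    best <- cand[which.max(accAt)]
    gap <- meanlog[k + 1L] - meanlog[k]
    expect_lt(abs(lthr[k] - best), 0.1 * gap)
  }
})

test_that("classification is monotone and matches nearest-centre assignment", {
  p <- rep(c(1e-4, 0.05, 0.9, 20), each = 30)
  m <- fitThresholds(p, seed = 4L)
  thr <- classifierThresholds(m)
  expect_equal(classifyPowers(thr[1] / 2, m), "no_breathing")
  expect_equal(classifyPowers(thr[3] * 2, m), "deep_inspiration")
  expect_equal(classifyPowers(thr[2], m), "free_breathing")  # boundary: upper
  grid <- exp(seq(log(1e-6), log(100), length.out = 500))
  cls <- match(classifyPowers(grid, m), breathingClasses())
  expect_true(all(diff(cls) >= 0))                 # monotone in power
  nearest <- apply(abs(outer(log(grid + m@logEpsilon), m@centersLog, "-")),
                   1, which.min)
  expect_equal(cls, as.integer(nearest))
})

test_that("metrics match hand-counted confusion matrices", {
  cls <- breathingClasses()
  truth <- rep(cls, each = 5)
  m <- evaluateClassification(truth, truth)
  expect_true(all(sensitivity(m) == 1) && all(specificity(m) == 1))
  expect_equal(accuracy(m), 1)

  ## two-class toy: TP=3 FN=1 TN=4 FP=2 for the breath_hold class
  truth2 <- c(rep("breath_hold", 4), rep("free_breathing", 6))
  pred2 <- c("breath_hold", "breath_hold", "breath_hold", "free_breathing",
             "breath_hold", "breath_hold", rep("free_breathing", 4))
  m2 <- evaluateClassification(pred2, truth2)
  expect_equal(sensitivity(m2)[["breath_hold"]], 0.75)
  expect_equal(specificity(m2)[["breath_hold"]], 2 / 3)
  expect_equal(accuracy(m2), 0.7)

  ## permuting the label names leaves the overall accuracy unchanged
  perm <- setNames(cls[c(3, 1, 4, 2)], cls)
  m2p <- evaluateClassification(unname(perm[pred2]), unname(perm[truth2]))
  expect_equal(accuracy(m2p), accuracy(m2))

  ## a class absent from the truth has undefined sensitivity, not 0
  expect_true(is.na(sensitivity(m2)[["no_breathing"]]))
  expect_false(is.na(specificity(m2)[["no_breathing"]]))
  expect_error(evaluateClassification(pred2, truth2[-1]), "equal length")
  expect_error(evaluateClassification(c(pred2, "x"), c(truth2, "x")),
               "outside the class set")
})

test_that("median windowed power increases over the four classes", {
  ## displacement-domain check of the class-power ordering
  tr <- concatTraces(generateIdleTrace(120),
                     generateSinusoidTrace(0.25, 4, 60),
                     generateDibhTrace(duration = 232))
  set.seed(32)
  sig <- movingAverage(displacement(tr) + rnorm(sampleCount(tr), 0, 0.3), 17)
  pow <- powerValues(windowedPower(sig, 68))
  lab <- windowMajorityLabels(classLabels(tr), 68)
  med <- vapply(breathingClasses(), function(cl) median(pow[lab == cl]),
                numeric(1))
  expect_true(all(diff(med) > 0))
})
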