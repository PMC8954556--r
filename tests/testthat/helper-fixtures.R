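## Shared fixtures, built lazily and memoised across test files.
## All randomness is seeded; the synthetic corpus reproduces the emulated
## emulated treatment-room conditions (interference-to-breathing power ratio 5, 17 Hz,
## 11 target bins centred on 25, 7 reference bins).

.fixtures <- new.env(parent = emptyenv())

withFixture <- function(name, expr) {
  if (!exists(name, envir = .fixtures)) {
    assign(name, force(expr), envir = .fixtures)
  }
  get(name, envir = .fixtures)
}

fixtureSiteSeed <- 42L

fixtureCfg <- function(duration, seed, ...) {
  sceneConfig(duration = duration, siteSeed = fixtureSiteSeed, seed = seed,
              ...)
}

## calibration protocol: all four classes, in session-like blocks
calibTrace <- function() {
  concatTraces(generateIdleTrace(60),
               generateSinusoidTrace(0.25, 4, 60),
               generateDibhTrace(duration = 116))
}

## evaluation session traces: long idle block in one scene (idle room),
## DIBH-heavy blocks in the others
evalTraces <- function() {
  list(concatTraces(generateIdleTrace(500),
                    generateSinusoidTrace(0.25, 4, 60),
                    generateDibhTrace(duration = 116)),
       concatTraces(generateSinusoidTrace(0.25, 4, 120),
                    generateDibhTrace(duration = 232),
                    generateSinusoidTrace(0.25, 4, 60)),
       concatTraces(generateDibhTrace(duration = 348),
                    generateSinusoidTrace(0.25, 4, 60)))
}

evalSpeedProfiles <- function() {
  list(speedProfile(c(150, 120, 200, 206), c(0.9, 1, 0.7, 0.85)),
       speedProfile(c(100, 100, 100, 112), c(1, 0.7, 0.85, 0.95)),
       speedProfile(c(120, 90, 110, 88), c(0.8, 1, 0.9, 0.75)))
}

trainSpeedProfile <- function() {
  speedProfile(c(40, 20, 60, 40, 50, 30), c(0.8, 0, 1, 0.5, 0.9, 0.7))
}

## interference-only training recording and the RB noise profile
fixtureTrainScene <- function() withFixture("trainScene", {
  cfg <- fixtureCfg(240, seed = 101L)
  composeScene(cfg, generateIdleTrace(240), trainSpeedProfile())
})

fixtureRbProfile <- function() withFixture("rbProfile", {
  buildNoiseProfile(fixtureTrainScene()@scene, targetZone = 20:30,
                    arch = "rb", seed = 5L)
})

fixtureSbProfile <- function() withFixture("sbProfile", {
  buildNoiseProfile(fixtureTrainScene()@scene, targetZone = 20:30,
                    arch = "sb", seed = 5L)
})

## breathing-only calibration recording (gantry parked)
fixtureCalibScene <- function() withFixture("calibScene", {
  cfg <- fixtureCfg(236, seed = 102L)
  composeScene(cfg, calibTrace(), NULL)
})

fixtureDetRb <- function() withFixture("detRb", {
  localizeTarget(fixtureCalibScene()@scene, fixtureRbProfile(), seed = 5L)
})

## thresholds for the gantry group, fitted on a gantry-active calibration
fixtureDetRbGantry <- function() withFixture("detRbGantry", {
  cfg <- fixtureCfg(236, seed = 103L)
  sp <- speedProfile(c(60, 60, 56, 60), c(0.9, 0.6, 1, 0.75))
  calib <- composeScene(cfg, calibTrace(), sp)
  calibrateThresholds(calib@scene, fixtureDetRb(), seed = 5L)
})

fixtureDetSb <- function() withFixture("detSb", {
  prof <- fixtureSbProfile()
  localizeTarget(fixtureCalibScene()@scene, prof, nTargetBins = 1L,
                 searchBins = prof@model@targetBins, seed = 5L)
})

## gantry-active evaluation corpus (~25 min) and its monitoring results
fixtureEvalCorpus <- function() withFixture("evalCorpus", {
  trs <- evalTraces(); sps <- evalSpeedProfiles()
  lapply(seq_along(trs), function(i) {
    cfg <- fixtureCfg(sampleCount(trs[[i]]) / 17, seed = 110L + i)
    composeScene(cfg, trs[[i]], sps[[i]])
  })
})

fixtureEvalResults <- function() withFixture("evalResults", {
  det <- fixtureDetRbGantry()
  scenes <- fixtureEvalCorpus()
  pred <- character(0); truth <- character(0)
  for (sc in scenes) {
    res <- runMonitoring(sc@scene, det, rateWindowS = NULL)
    pred <- c(pred, classLabels(res))
    truth <- c(truth, windowMajorityLabels(classLabels(sc),
                                           det@classifier@windowSamples))
  }
  list(pred = pred, truth = truth)
})

## matched interference-free corpus for the single-bin chain
fixtureSbResults <- function() withFixture("sbResults", {
  det <- fixtureDetSb()
  trs <- evalTraces()
  pred <- character(0); truth <- character(0)
  for (i in seq_along(trs)) {
    cfg <- fixtureCfg(sampleCount(trs[[i]]) / 17, seed = 120L + i)
    sc <- composeScene(cfg, trs[[i]], NULL)
    res <- runMonitoring(sc@scene, det, rateWindowS = NULL)
    pred <- c(pred, classLabels(res))
    truth <- c(truth, windowMajorityLabels(classLabels(sc),
                                           det@classifier@windowSamples))
  }
  list(pred = pred, truth = truth)
})
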