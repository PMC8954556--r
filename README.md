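# uwbreath

Respiratory motion recovery and breathing-pattern classification from
single-antenna ultra-wideband (UWB) radar during dynamic radiotherapy
delivery.

## The problem

Respiratory gating and deep-inspiration breath hold (DIBH) need a
real-time, contactless surrogate of chest-wall motion. A low-cost UWB
impulse radar sees the chest echo in ~11 adjacent range bins (~5 cm each)
of its fast–slow time matrix, sampled at 17 Hz — but during volumetric
modulated arc therapy (VMAT) the rotating linac gantry injects broadband
interference into the same bins at several times the breathing power.

`uwbreath` implements the processing chain for this setting:

* **Adaptive interference estimation.** Multilayer perceptrons map the
  instantaneous complex samples of 7 interference-only *reference* bins to
  the interference in the target bins — a single-bin variant
  (14 → 56 → 28 → 2, one complex bin) and a range-bin variant
  (14 → 126 → 22 → 22, eleven complex bins), trained on a recording made
  with no patient in the room (70/15/15 split, z-scored channels, early
  stopping). The estimate uses only the current sample, so subtraction is
  causal and real-time capable.
* **Range-bin weighted averaging (RBWA).** Each denoised bin is projected
  onto its first principal axis in the complex plane; bins are fused as
  `y[n] = Σ_b w_b p_b proj_b[n]` with power-proportional weights `w_b` and
  polarity signs `p_b` (bins whose waveform appears inverted are flipped
  back), giving a ≈ √N SNR gain for N bins.
* **Filtering and rate estimation.** A trailing moving average (17
  samples) removes residual broadband noise; the breathing rate is the
  dominant periodogram frequency in 0–0.5 Hz (0–30 breaths/min) of a
  trailing window, 0 during breath hold / empty room.
* **Classification.** The mean-removed power of a 68-sample moving window
  is split by three thresholds — midpoints between 1-D k-means (k = 4)
  cluster centres in the log-power domain, fitted per delivery group
  (with/without gantry) — into `no_breathing < breath_hold <
  free_breathing < deep_inspiration`, scored one-vs-rest by sensitivity
  TP/(TP+FN), specificity TN/(TN+FP) and overall accuracy.
* **A seeded synthetic scene generator** emulating the respiratory-motion
  phantom (0.25 Hz, 4 mm sinusoid; parametric DIBH sequences) and the
  treatment room (latent broadband interference processes mixed into all
  bins through fixed per-site gains, calibrated to an
  interference-to-breathing power ratio of 5), so the whole chain runs and
  is tested without any recorded data.

The clinical workflow has three phases, mirrored by the API and CLI:
`buildNoiseProfile()` (no patient in the room, delivery running),
`localizeTarget()` / `calibrateThresholds()` (patient set up, gantry
parked), `runMonitoring()` (treatment time, fully causal). See the
methods vignette (`vignettes/uwbreath-methods.Rmd`) for the model details
and design rationale.

## Worked example

```r
library(uwbreath)

## 1. Phase 1: record the treatment delivery with no patient in the room
##    and train the range-bin interference estimator
cfgTrain <- sceneConfig(duration = 240, siteSeed = 42, seed = 101,
                        interferencePowerRatio = 5)
delivery <- composeScene(cfgTrain, generateIdleTrace(240),
                         speedProfile(c(40, 20, 60, 40, 50, 30),
                                      c(0.8, 0, 1, 0.5, 0.9, 0.7)))
profile <- buildNoiseProfile(delivery@scene, targetZone = 20:30, arch = "rb")

## 2. Phase 2: localize the breathing target on a calibration sequence
##    (gantry parked) and fit the power thresholds
calib <- concatTraces(generateIdleTrace(60),
                      generateSinusoidTrace(0.25, 4, 60),
                      generateDibhTrace(duration = 116))
cfgCalib <- sceneConfig(duration = 236, siteSeed = 42, seed = 102)
detect <- localizeTarget(composeScene(cfgCalib, calib, NULL)@scene, profile)

## 3. Refit thresholds for the gantry-active group, then monitor a DIBH
##    session delivered under full gantry motion
cfgG <- sceneConfig(duration = 236, siteSeed = 42, seed = 103)
detectG <- calibrateThresholds(
  composeScene(cfgG, calib, speedProfile(c(120, 116), c(0.9, 1)))@scene,
  detect)

cfgRun <- sceneConfig(duration = 232, siteSeed = 42, seed = 104)
session <- composeScene(cfgRun, generateDibhTrace(duration = 232),
                        speedProfile(c(120, 112), c(1, 0.8)))
res <- runMonitoring(session@scene, detectG)
res
#> MonitoringResult: 3944 samples, 3877 classified windows
#>   predicted: no_breathing=0, breath_hold=1386, free_breathing=1353, deep_inspiration=1138

truth <- windowMajorityLabels(classLabels(session), 68)
evaluateClassification(classLabels(res), truth)
#> ClassMetrics: overall accuracy 0.9528
#>                  sensitivity specificity
#> no_breathing              NA      1.0000
#> breath_hold           0.9059      1.0000
#> free_breathing        0.9706      0.9741
#> deep_inspiration      1.0000      0.9590
```

Despite gantry interference at five times the breathing power, 95% of the
4-second windows of the DIBH session are classified into the correct
breathing state; the residual errors sit almost entirely in windows that
straddle a maneuver boundary (mostly breath-hold windows bordering a deep
inhale or exhale, hence the 0.91 hold sensitivity). `no_breathing` is `NA`
because the session never has an empty couch — absent classes report
undefined, not zero, sensitivity.

Breathing-rate estimation on a free-breathing session under the same
interference settles at the phantom's programmed 15 breaths per minute:

```r
cfgSin <- sceneConfig(duration = 90, siteSeed = 42, seed = 105)
free <- composeScene(cfgSin, generateSinusoidTrace(0.25, 4, 90),
                     speedProfile(90, 1))
resFree <- runMonitoring(free@scene, detectG)
tail(resFree@rateSeries, 3)
#>    time_s      bpm
#> 59     88 14.94141
#> 60     89 14.94141
#> 61     90 14.94141
```

A command-line interface wraps the same workflow
(`system.file("scripts", "uwbreath", package = "uwbreath")`):

```sh
uwbreath simulate    --config scene.yaml --out scene.bin --labels labels.csv
uwbreath train-noise --arch rb --in interference.bin --zone 20:30 --profile site1.profile
uwbreath localize    --in breathing.bin --profile site1.profile --out site1.detect
uwbreath run         --in combined.bin --detect site1.detect --out recovered.csv --classes classes.csv
uwbreath evaluate    --pred classes.csv --truth labels.csv --report metrics.csv
```

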