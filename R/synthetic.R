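#' @include AllClasses.R
NULL

.sampleCountOf <- function(duration, rate) {
  n <- duration * rate
  if (abs(n - round(n)) > 1e-8)
    stop("duration * rate must yield an integer sample count")
  as.integer(round(n))
}

#' Generate a sinusoidal breathing trace
#'
#' The basic phantom pattern: `d[n] = A sin(2 pi f n / rate)`. A zero
#' amplitude produces an all-zero trace labelled `no_breathing`; otherwise
#' all samples are labelled `free_breathing`.
#'
#' @param freq Breathing frequency in Hz (default 0.25, i.e. 15 breaths/min).
#' @param amplitudeMm Displacement amplitude in mm (default 4).
#' @param duration Trace duration in seconds.
#' @param rate Sampling rate in Hz (default 17); must exceed `2 * freq`.
#' @return A [DisplacementTrace-class].
#' @export
#' @examples
#' tr <- generateSinusoidTrace(0.25, 4, 70)
#' sampleCount(tr)           # 1190
#' diff(range(displacement(tr)))  # peak-to-peak 8 mm
generateSinusoidTrace <- function(freq = 0.25, amplitudeMm = 4, duration,
                                  rate = 17) {
  if (freq < 0) stop("freq must be >= 0")
  if (amplitudeMm < 0) stop("amplitude must be >= 0")
  if (duration <= 0) stop("duration must be positive")
  if (rate <= 2 * freq)
    stop("rate must exceed twice the breathing frequency (aliasing)")
  n <- .sampleCountOf(duration, rate)
  idx <- 0:(n - 1L)
  d <- amplitudeMm * sin(2 * pi * freq * idx / rate)
  lab <- rep(if (amplitudeMm == 0) "no_breathing" else "free_breathing", n)
  displacementTrace(d, rate = rate, labels = lab)
}

#' Generate an idle (no subject) trace
#'
#' @param duration Duration in seconds.
#' @param rate Sampling rate in Hz.
#' @return An all-zero [DisplacementTrace-class] labelled `no_breathing`.
#' @export
generateIdleTrace <- function(duration, rate = 17) {
  generateSinusoidTrace(freq = 0.25, amplitudeMm = 0, duration = duration,
                        rate = rate)
}

#' Generate a deep-inspiration breath-hold (DIBH) trace
#'
#' A parametric ramp-plateau-release family emulating a phantom DIBH
#' sequence. Each cycle consists of free breathing at `baseAmp`, a
#' deep-inspiration phase (2.25 periods of a `deepAmp` oscillation, ending at
#' the inhaled peak), a breath-hold plateau at `deepAmp` carrying a
#' sub-millimetre residual oscillation, and a deep release (2.25 periods
#' returning to baseline). Labels follow the four breathing classes:
#' the deep phases are `deep_inspiration`, the plateau `breath_hold`, and
#' the base oscillation `free_breathing`. Cycles repeat until `duration` is
#' filled (the last cycle may be truncated).
#'
#' @param baseAmp Free-breathing amplitude (mm), default 4.
#' @param deepAmp Deep-inspiration amplitude and plateau level (mm); must
#'   exceed `baseAmp`. Default 12.
#' @param holdS Plateau duration in seconds (default 30); `holdS = 0` emits
#'   no breath-hold samples.
#' @param breathFreq Breathing frequency in Hz, default 0.25.
#' @param duration Total duration in seconds.
#' @param rate Sampling rate in Hz, default 17.
#' @param freeS Free-breathing duration per cycle in seconds, default 20.
#' @param residualAmp Residual oscillation amplitude during the hold (mm),
#'   default 0.9 (must stay below 1 mm).
#' @param residualFreq Residual oscillation frequency (Hz), default 0.3.
#' @return A [DisplacementTrace-class].
#' @export
#' @examples
#' tr <- generateDibhTrace(4, 12, 20, 0.25, duration = 112)
#' sampleCount(tr)   # 1904
#' table(classLabels(tr))
generateDibhTrace <- function(baseAmp = 4, deepAmp = 12, holdS = 30,
                              breathFreq = 0.25, duration, rate = 17,
                              freeS = 20, residualAmp = 0.9,
                              residualFreq = 0.3) {
  if (!(deepAmp > baseAmp) || !(baseAmp > 0))
    stop("need deepAmp > baseAmp > 0")
  if (holdS < 0) stop("holdS must be >= 0")
  if (holdS >= duration) stop("holdS must be smaller than duration")
  if (residualAmp >= 1)
    stop("hold residual must stay sub-millimetre (residualAmp < 1)")
  n <- .sampleCountOf(duration, rate)
  tAt <- function(ns) (seq_len(ns) - 1L) / rate
  deepS <- 2.25 / breathFreq
  segs <- list(
    list(ns = .sampleCountOf(freeS, rate), lab = "free_breathing",
         fn = function(t) baseAmp * sin(2 * pi * breathFreq * t)),
    list(ns = .sampleCountOf(deepS, rate), lab = "deep_inspiration",
         fn = function(t) deepAmp * sin(2 * pi * breathFreq * t)),
    list(ns = .sampleCountOf(holdS, rate), lab = "breath_hold",
         fn = function(t) deepAmp + residualAmp *
           sin(2 * pi * residualFreq * t)),
    list(ns = .sampleCountOf(deepS, rate), lab = "deep_inspiration",
         fn = function(t) deepAmp * cos(2 * pi * breathFreq * t)))
  segs <- Filter(function(s) s$ns > 0L, segs)
  d <- numeric(0); lab <- character(0)
  while (length(d) < n) {
    for (s in segs) {
      d <- c(d, s$fn(tAt(s$ns)))
      lab <- c(lab, rep(s$lab, s$ns))
      if (length(d) >= n) break
    }
  }
  displacementTrace(d[seq_len(n)], rate = rate, labels = lab[seq_len(n)])
}

#' Concatenate displacement traces
#'
#' @param ... [DisplacementTrace-class] objects with equal sampling rates.
#' @return A single concatenated [DisplacementTrace-class].
#' @export
concatTraces <- function(...) {
  trs <- list(...)
  if (length(trs) == 1L && is.list(trs[[1L]]) && !is(trs[[1L]], "DisplacementTrace"))
    trs <- trs[[1L]]
  rates <- vapply(trs, sampleRate, numeric(1))
  if (length(unique(rates)) != 1L) stop("traces must share a sampling rate")
  displacementTrace(unlist(lapply(trs, displacement)), rate = rates[1L],
                    labels = unlist(lapply(trs, classLabels)))
}

#' Build a gantry speed profile
#'
#' @param durations Segment durations in seconds.
#' @param speeds Relative gantry speed per segment, each in `[0, 1]`.
#' @return A data frame with columns `duration` and `speed`.
#' @export
speedProfile <- function(durations, speeds) {
  if (length(durations) != length(speeds) || length(durations) == 0L)
    stop("durations and speeds must be non-empty and of equal length")
  if (any(speeds < 0 | speeds > 1)) stop("speeds must lie in [0, 1]")
  if (any(durations <= 0)) stop("durations must be positive")
  data.frame(duration = durations, speed = speeds)
}

.speedTrack <- function(profile, rate, n) {
  if (is.null(profile) || nrow(profile) == 0L) stop("empty speed profile")
  ns <- vapply(profile$duration, .sampleCountOf, integer(1), rate = rate)
  if (sum(ns) != n)
    stop("speed profile durations must sum to the scene duration")
  rep(profile$speed, ns)
}

## latent broadband complex sources, unit variance, mildly smoothed so the
## band is finite but still far wider than the 0-0.5 Hz breathing band
.latentSources <- function(L, n) {
  S <- matrix(complex(real = rnorm(L * n), imaginary = rnorm(L * n)) /
                sqrt(2), L, n)
  if (n >= 2L) {
    a <- 0.4
    Sm <- S
    Sm[, -1L] <- (S[, -1L] + a * S[, -ncol(S)]) / sqrt(1 + a^2)
    S <- Sm
  }
  S
}

.complexNoise <- function(nr, nc, power) {
  matrix(complex(real = rnorm(nr * nc), imaginary = rnorm(nr * nc)) *
           sqrt(power / 2), nr, nc)
}

#' Generate gantry interference
#'
#' Builds an interference-only fast-slow time matrix: a small number of
#' latent broadband processes, amplitude-modulated by the gantry speed
#' profile and mixed into all bins through fixed per-bin complex gains, plus
#' the thermal noise floor. The mixing makes the interference correlated
#' across bins, which is what allows reference-bin estimators to predict the
#' target-bin interference. The overall level is calibrated so that the mean
#' interference power in the target bins during nonzero-speed segments is
#' `interferencePowerRatio` times the configured breathing power
#' ([referenceBreathingPower()]).
#'
#' @param cfg A [SceneConfig-class].
#' @param profile A speed profile from [speedProfile()]; durations must sum
#'   to `cfg` duration.
#' @return A [RangeBinMatrix-class] over all bins.
#' @export
generateGantryInterference <- function(cfg, profile) {
  n <- .sampleCountOf(cfg@duration, cfg@rate)
  speed <- .speedTrack(profile, cfg@rate, n)
  L <- cfg@nLatentSources
  ## mixing gains belong to the site geometry, not to the recording
  M <- .withSeed(cfg@siteSeed + 202L, function()
    matrix(complex(real = rnorm(cfg@nBins * L),
                   imaginary = rnorm(cfg@nBins * L)) / sqrt(2),
           cfg@nBins, L))
  .withSeed(cfg@seed + 202L, function() {
    vals <- .complexNoise(cfg@nBins, n, cfg@noiseFloorPower)
    nz <- speed > 0
    if (any(nz) && cfg@interferencePowerRatio > 0) {
      S <- .latentSources(L, n)
      rowPow <- rowSums(Mod(M)^2)
      meanTarget <- mean(rowPow[cfg@targetBins])
      msqSpeed <- mean(speed[nz]^2)
      alpha <- sqrt(cfg@interferencePowerRatio * referenceBreathingPower(cfg) /
                      (meanTarget * msqSpeed))
      mixed <- (M %*% S) * matrix(speed, cfg@nBins, n, byrow = TRUE)
      vals <- vals + alpha * mixed
    }
    rangeBinMatrix(vals, rate = cfg@rate, bins = seq_len(cfg@nBins))
  })
}

#' Project a displacement trace into the target range bins
#'
#' Applies the per-bin response model of [SceneConfig-class]: each target
#' bin carries a static clutter phasor plus a displacement-proportional
#' complex perturbation and a carrier-phase rotation
#' `phaseGain * 4 pi d / lambda`. Non-target bins are zero. Bins differ in
#' gain magnitude and phase; bins with a negative coupling slope appear
#' polarity-inverted.
#'
#' @param trace A [DisplacementTrace-class] with the scene's sampling rate.
#' @param cfg A [SceneConfig-class].
#' @return A [RangeBinMatrix-class] over all bins (zeros off target).
#' @export
projectTarget <- function(trace, cfg) {
  if (abs(sampleRate(trace) - cfg@rate) > 1e-9)
    stop("trace rate must match the scene rate")
  d <- displacement(trace)
  n <- length(d)
  vals <- matrix(0 + 0i, cfg@nBins, n)
  phase <- cfg@phaseGain * 4 * pi * (d / 1000) / cfg@wavelength
  carrier <- exp(1i * phase)
  for (k in seq_along(cfg@targetBins)) {
    b <- cfg@targetBins[k]
    vals[b, ] <- cfg@targetGains[k] *
      (1 + cfg@couplingSlopes[k] * d / cfg@displacementRef) * carrier
  }
  rangeBinMatrix(vals, rate = cfg@rate, bins = seq_len(cfg@nBins))
}

#' Compose a full radar scene
#'
#' Combined scene = projected breathing target + gantry interference +
#' circular complex thermal noise, with every addend retained as ground
#' truth. Deterministic for a fixed `cfg` seed.
#'
#' @param cfg A [SceneConfig-class].
#' @param trace A [DisplacementTrace-class]; its length must equal the scene
#'   sample count.
#' @param profile A speed profile ([speedProfile()]), or `NULL` for an
#'   interference-free scene (gantry parked; only the noise floor remains).
#' @return A [RadarScene-class].
#' @export
#' @examples
#' cfg <- sceneConfig(duration = 20, seed = 3)
#' tr <- generateSinusoidTrace(0.25, 4, 20)
#' sp <- speedProfile(20, 1)
#' sc <- composeScene(cfg, tr, sp)
composeScene <- function(cfg, trace, profile = NULL) {
  n <- .sampleCountOf(cfg@duration, cfg@rate)
  if (sampleCount(trace) != n)
    stop("trace length does not match the scene duration")
  if (is.null(profile)) profile <- speedProfile(cfg@duration, 0)
  target <- projectTarget(trace, cfg)
  interference <- generateGantryInterference(cfg, profile)
  thermal <- .withSeed(cfg@seed + 303L, function()
    rangeBinMatrix(.complexNoise(cfg@nBins, n, cfg@noiseFloorPower),
                   rate = cfg@rate, bins = seq_len(cfg@nBins)))
  combined <- rangeBinMatrix(target@values + interference@values +
                               thermal@values,
                             rate = cfg@rate, bins = seq_len(cfg@nBins))
  truth <- new("SceneGroundTruth", displacement = trace,
               cleanTarget = restrictBins(target, cfg@targetBins),
               interferenceOnly = interference, thermalNoise = thermal)
  new("RadarScene", scene = combined, truth = truth, config = cfg)
}
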