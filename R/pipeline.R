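#' @include AllClasses.R noise-estimation.R enhancement.R classification.R
NULL

## narrowband line detector: ratio of the strongest spectral line inside
## the breathing band to the median line power of the whole spectrum.
## Breathing concentrates in one or two lines below 0.5 Hz, while gantry
## interference (and the noise floor) spreads over the full band, so the
## ratio stays near the broadband extreme-value level (~10) without a
## subject and grows by an order of magnitude with one.
.breathingLineRatio <- function(z, rate, fmax = 0.5) {
  zc <- z - mean(z)
  if (mean(Mod(zc)^2) < 1e-30) return(0)
  P <- Mod(stats::fft(zc))^2
  n <- length(z)
  f <- (seq_len(n) - 1L) * rate / n
  f <- pmin(f, rate - f)                 # two-sided -> absolute frequency
  inBand <- f <= fmax & f > 0
  if (!any(inBand)) return(0)
  max(P[inBand]) / max(stats::median(P), 1e-300)
}

## total mean-removed power of a complex bin inside the breathing band
.bandPower <- function(z, rate, fmax = 0.5) {
  zc <- z - mean(z)
  P <- Mod(stats::fft(zc))^2 / length(z)^2
  n <- length(z)
  f <- (seq_len(n) - 1L) * rate / n
  f <- pmin(f, rate - f)
  sum(P[f <= fmax & f > 0])
}

#' Build the noise profile for a radar location
#'
#' The pre-treatment, no-patient phase: from an interference-only recording
#' (treatment delivery executed with nobody in the room), selects the
#' highest-power interference bins outside the configured patient zone as
#' noise references, trains the chosen interference estimator for the
#' patient-zone bins, and returns the radar profile for this location.
#'
#' The recording is refused when the candidate patient zone shows energy
#' concentrated in the breathing band (0-0.5 Hz), i.e. when somebody (or
#' the phantom) was breathing in front of the radar during acquisition.
#'
#' @param x Interference-only [RangeBinMatrix-class] over all bins.
#' @param targetZone Contiguous candidate patient bins (e.g. 20:30).
#' @param arch `"rb"` (default) to estimate interference in every zone bin,
#'   or `"sb"` for the single centre bin.
#' @param nReferenceBins Number of reference bins to select, default 7.
#' @param id Location identifier stored in the profile.
#' @param seed Training seed.
#' @param control,split Passed to [trainEstimator()].
#' @param breathingLineLimit Refuse when a zone bin carries a breathing-band
#'   spectral line stronger than this multiple of its median line power,
#'   default 80 (gantry speed steps modulate the broadband interference and
#'   can push broadband-only lines to a few tens of times the median; a
#'   breathing line sits orders of magnitude above it).
#' @return A [RadarProfile-class].
#' @export
buildNoiseProfile <- function(x, targetZone, arch = c("rb", "sb"),
                              nReferenceBins = 7L, id = "site",
                              seed = 1L, control = list(),
                              split = trainingSplit(),
                              breathingLineLimit = 80) {
  arch <- match.arg(arch)
  if (!is(x, "RangeBinMatrix") || ncol(x@values) == 0L)
    stop("empty recording")
  targetZone <- as.integer(targetZone)
  rate <- x@rate
  vars <- apply(x@values, 1L, function(z) mean(Mod(z - mean(z))^2))
  zoneIdx <- match(targetZone, x@bins)
  if (any(is.na(zoneIdx))) stop("target zone bins missing from recording")
  for (i in zoneIdx) {
    if (.breathingLineRatio(x@values[i, ], rate) > breathingLineLimit)
      stop("breathing-band energy detected in the candidate target zone; ",
           "record the noise profile with no subject in the room")
  }
  outside <- setdiff(seq_along(x@bins), zoneIdx)
  ord <- outside[order(vars[outside], decreasing = TRUE)]
  refBins <- sort(x@bins[ord[seq_len(nReferenceBins)]])
  tgtBins <- if (arch == "sb")
    targetZone[(length(targetZone) + 1L) %/% 2L] else targetZone
  model <- trainEstimatorFromRecording(x, refBins, tgtBins, arch = arch,
                                       seed = seed, control = control,
                                       split = split)
  new("RadarProfile", id = id, referenceBins = refBins, model = model,
      created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
}

## best contiguous run of `width` bins by breathing-band power
.bestRun <- function(bandPow, bins, width) {
  if (length(bins) < width) stop("fewer bins than the requested run width")
  ## bins are assumed sorted and contiguous in index space
  best <- NULL; bestSum <- -Inf
  for (s in seq_len(length(bins) - width + 1L)) {
    if (bins[s + width - 1L] - bins[s] != width - 1L) next
    sm <- sum(bandPow[s:(s + width - 1L)])
    if (sm > bestSum) { bestSum <- sm; best <- bins[s:(s + width - 1L)] }
  }
  list(run = best, sum = bestSum)
}

#' Localize the breathing target and build the detection profile
#'
#' The patient-setup phase, run without background motion: finds the
#' contiguous run of bins with the highest breathing-band (0-0.5 Hz) power,
#' computes the range-bin averaging weights and polarities on those bins,
#' fits the power-classifier thresholds on the recording (which should be a
#' calibration sequence containing all four breathing classes), and
#' combines everything with the radar noise profile into a detection
#' profile.
#'
#' @param x Breathing-only [RangeBinMatrix-class] over all bins.
#' @param profile The [RadarProfile-class] of this location.
#' @param nTargetBins Width of the target run, default 11.
#' @param searchBins Bins to search, default all bins in `x` except the
#'   profile's reference bins.
#' @param maWindow Moving-average window for the recovered signal, default
#'   17 samples.
#' @param classifierWindow Power window for classification, default 68.
#' @param floorFactor A run qualifies only if its mean breathing-band power
#'   exceeds `floorFactor` times the median over all bins of the recording;
#'   otherwise no subject is detected. Default 10.
#' @param referenceBin Polarity reference bin, default the strongest.
#' @param seed Seed for threshold fitting.
#' @return A [DetectionProfile-class].
#' @export
localizeTarget <- function(x, profile, nTargetBins = 11L, searchBins = NULL,
                           maWindow = 17L, classifierWindow = 68L,
                           floorFactor = 10, referenceBin = NULL,
                           seed = 1L) {
  if (!is(x, "RangeBinMatrix") || ncol(x@values) == 0L)
    stop("empty recording")
  if (is.null(searchBins))
    searchBins <- setdiff(x@bins, profile@referenceBins)
  searchBins <- sort(as.integer(searchBins))
  allBand <- vapply(seq_along(x@bins), function(i)
    .bandPower(x@values[i, ], x@rate), numeric(1))
  idx <- match(searchBins, x@bins)
  bandPow <- allBand[idx]
  run <- .bestRun(bandPow, searchBins, as.integer(nTargetBins))
  ## the subject floor is judged against the whole recording, so narrow
  ## searches (e.g. the single-bin chain) still have a noise baseline
  med <- stats::median(allBand)
  if (is.null(run$run) ||
      run$sum / nTargetBins <= floorFactor * max(med, 1e-300))
    stop("no subject detected: no range-bin run exceeds the ",
         "breathing-band power floor")
  ## denoise with the location's estimator when it covers the run
  # (prior to treatment there is no interference, but running the same chain
  # as monitoring keeps the calibration consistent)
  useModel <- all(run$run %in% profile@model@targetBins)
  den <- if (useModel) restrictBins(denoise(profile@model, x), run$run)
  else restrictBins(x, run$run)
  w <- computeWeightsAndPolarity(den, referenceBin = referenceBin)
  sig <- movingAverage(rangeBinWeightedAverage(den, w), maWindow)
  pow <- windowedPower(sig, classifierWindow)
  clf <- fitThresholds(pow, seed = seed)
  new("DetectionProfile", radar = profile, targetBins = run$run,
      weights = w, maWindow = as.integer(maWindow), classifier = clf)
}

#' Refit the classifier thresholds on a calibration recording
#'
#' Breathing patterns are grouped by delivery state (with / without gantry
#' motion); thresholds are fitted per group. This helper reruns the full
#' recovery chain of a detection profile on a calibration recording from
#' the target group (all four classes present) and returns the profile with
#' refitted thresholds.
#'
#' @param x Calibration [RangeBinMatrix-class] over all bins.
#' @param detect A [DetectionProfile-class].
#' @param seed Seed for threshold fitting.
#' @return The updated [DetectionProfile-class].
#' @export
calibrateThresholds <- function(x, detect, seed = 1L) {
  res <- runMonitoring(x, detect, rateWindowS = NULL)
  clf <- fitThresholds(res@powers, seed = seed)
  new("DetectionProfile", radar = detect@radar,
      targetBins = detect@targetBins, weights = detect@weights,
      maWindow = detect@maWindow, classifier = clf)
}

#' Run the monitoring phase
#'
#' The treatment-time chain, causal end to end: estimate and subtract the
#' interference in the target bins, project and fuse them by polarity-
#' corrected weighted averaging, filter with the trailing moving average,
#' classify the windowed power of every window, and estimate the breathing
#' rate on a trailing window at a fixed stride.
#'
#' @param x Combined [RangeBinMatrix-class] over all bins.
#' @param detect A [DetectionProfile-class] valid for this geometry.
#' @param rateWindowS Trailing window (s) for breathing-rate estimates,
#'   default 30; `NULL` skips rate estimation.
#' @param rateStrideS Stride (s) between rate estimates, default 1.
#' @return A [MonitoringResult-class]; window labels are aligned with the
#'   window start samples.
#' @export
runMonitoring <- function(x, detect, rateWindowS = 30, rateStrideS = 1) {
  model <- detect@radar@model
  if (!all(detect@targetBins %in% model@targetBins))
    stop("detection profile target bins are not covered by the estimator")
  den <- restrictBins(denoise(model, x), detect@targetBins)
  sig <- movingAverage(rangeBinWeightedAverage(den, detect@weights),
                       detect@maWindow)
  pow <- windowedPower(sig, detect@classifier@windowSamples)
  labels <- classifyPowers(pow, detect@classifier)
  starts <- seq.int(1L, sampleCount(sig) - detect@classifier@windowSamples + 1L)
  rateSeries <- data.frame(time_s = numeric(0), bpm = numeric(0))
  if (!is.null(rateWindowS)) {
    rate <- sig@rate
    nw <- as.integer(round(rateWindowS * rate))
    stride <- max(1L, as.integer(round(rateStrideS * rate)))
    ends <- seq.int(nw, sampleCount(sig), by = stride)
    if (length(ends) > 0L) {
      bpm <- vapply(ends, function(e)
        estimateBreathingRate(sig@samples[seq_len(e)], windowS = rateWindowS,
                              rate = rate), numeric(1))
      rateSeries <- data.frame(time_s = ends / rate, bpm = bpm)
    }
  }
  new("MonitoringResult", recovered = sig, powers = pow,
      windowLabels = labels, windowStarts = as.integer(starts),
      rateSeries = rateSeries)
}
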